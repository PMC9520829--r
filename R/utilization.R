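merge_episodes <- function(discharges, cohort) {
  check_columns(discharges, c("patient_id", "admit_date", "discharge_date"),
                "discharges")
  elig <- cohort %>% filter(.data$eligible) %>%
    select("patient_id", "followup_start", "followup_end")

  eps <- discharges %>%
    mutate(admit_date = as.Date(.data$admit_date),
           discharge_date = as.Date(.data$discharge_date)) %>%
    semi_join(elig, by = "patient_id")

  miss <- is.na(eps$discharge_date)
  if (any(miss)) {
    warn(sprintf("Skipped %d episode(s) with missing discharge date.", sum(miss)))
    eps <- eps[!miss, ]
  }
  if (!"admission_category" %in% names(eps)) eps$admission_category <- "emergent"
  if (!"died_in_hospital" %in% names(eps)) eps$died_in_hospital <- FALSE
  if (!"mrd_code" %in% names(eps)) eps$mrd_code <- NA_character_

  eps <- eps %>% arrange(.data$patient_id, .data$admit_date, .data$discharge_date)

  # merge overlapping or nested stays into single episodes so transfers
  # between wards cannot masquerade as 0-day readmissions (vectorized run
  # detection: a new episode starts when the admit date exceeds the running
  # maximum discharge date within the patient)
  n_eps <- nrow(eps)
  if (n_eps == 0) {
    merged <- eps
  } else {
    pid <- eps$patient_id
    a <- as.numeric(eps$admit_date)
    d <- as.numeric(eps$discharge_date)
    cm <- stats::ave(d, cumsum(!duplicated(pid)), FUN = cummax)
    prev_cm <- c(NA_real_, cm[-n_eps])
    new_run <- !duplicated(pid) | a > prev_cm
    run_id <- cumsum(new_run)
    first_i <- which(new_run)
    last_i <- c(first_i[-1] - 1L, n_eps)
    died_cs <- cumsum(eps$died_in_hospital)
    merged <- tibble(
      patient_id = pid[first_i],
      admit_date = eps$admit_date[first_i],
      discharge_date = as.Date(cm[last_i], origin = "1970-01-01"),
      mrd_code = eps$mrd_code[first_i],
      admission_category = eps$admission_category[first_i],
      died_in_hospital = (died_cs[last_i] - c(0, died_cs[last_i])[seq_along(last_i)]) > 0
    )
  }
  if (nrow(merged) < n_eps) {
    warn(sprintf("Merged %d overlapping hospital stay(s).", n_eps - nrow(merged)))
  }
  merged %>%
    left_join(elig, by = "patient_id") %>%
    mutate(in_window = .data$admit_date >= .data$followup_start &
             .data$admit_date < .data$followup_end)
}

#' Count hospital admissions over follow-up
#'
#' Counts, per eligible cohort member, hospital admissions with admission
#' date inside the half-open follow-up interval `[followup_start,
#' followup_end)`, both all-cause and COPD-related (most-responsible
#' diagnosis matching the case-definition code sets by prefix). Overlapping
#' or nested stays are merged into one episode first.
#'
#' @param discharges Discharge abstracts with `patient_id`, `admit_date`,
#'   `discharge_date`, and optionally `mrd_code`, `admission_category`,
#'   `died_in_hospital`.
#' @param cohort Cohort tibble with follow-up intervals.
#' @param case_def Code sets defining "COPD-related".
#' @param unplanned_only If `TRUE`, count only non-elective, non-transfer
#'   admissions.
#' @return Tibble: `patient_id`, `n_admissions_all`, `n_admissions_copd`,
#'   `any_admission` for every eligible cohort member (zeroes when no
#'   admission).
#' @export
count_admissions <- function(discharges, cohort,
                             case_def = copd_case_definition(),
                             unplanned_only = FALSE, .episodes = NULL) {
  eps <- (.episodes %||% merge_episodes(discharges, cohort)) %>%
    filter(.data$in_window)
  if (unplanned_only) {
    eps <- eps %>% filter(!.data$admission_category %in% c("elective", "transfer"))
  }
  counts <- eps %>%
    mutate(is_copd = matches_case_definition(.data$mrd_code, case_def)) %>%
    group_by(.data$patient_id) %>%
    summarise(n_admissions_all = n(),
              n_admissions_copd = sum(.data$is_copd),
              .groups = "drop")
  cohort %>%
    filter(.data$eligible) %>%
    select("patient_id") %>%
    left_join(counts, by = "patient_id") %>%
    mutate(n_admissions_all = dplyr::coalesce(.data$n_admissions_all, 0L),
           n_admissions_copd = dplyr::coalesce(as.integer(.data$n_admissions_copd), 0L),
           any_admission = .data$n_admissions_all >= 1L)
}

#' Flag 30-day readmissions
#'
#' A 30-day readmission is an unplanned (neither elective nor transfer)
#' admission whose admit date falls in the half-open-from-below interval
#' `(discharge_date, discharge_date + 30]` of the immediately preceding
#' episode, both episodes inside follow-up. Day 30 counts; day 0 (same-day
#' transfer-back) does not, and episodes are merged before pairing so
#' nested stays cannot create artifactual readmissions. Each qualifying
#' consecutive pair increments the count.
#'
#' @inheritParams count_admissions
#' @return Tibble: `patient_id`, `n_readmissions_30d`, `any_readmission_30d`
#'   for every eligible cohort member.
#' @export
flag_30day_readmissions <- function(discharges, cohort, .episodes = NULL) {
  eps <- (.episodes %||% merge_episodes(discharges, cohort)) %>%
    filter(.data$in_window) %>%
    arrange(.data$patient_id, .data$admit_date)
  m <- nrow(eps)
  same_patient <- if (m > 0) c(FALSE, eps$patient_id[-m] == eps$patient_id[-1]) else logical()
  gap <- if (m > 0) c(NA, as.numeric(eps$admit_date[-1] - eps$discharge_date[-m])) else numeric()
  is_readmission <- same_patient & !is.na(gap) & gap > 0 & gap <= 30 &
    !eps$admission_category %in% c("elective", "transfer")
  flags <- tibble(patient_id = eps$patient_id,
                  is_readmission = is_readmission) %>%
    group_by(.data$patient_id) %>%
    summarise(n_readmissions_30d = sum(.data$is_readmission), .groups = "drop")
  cohort %>%
    filter(.data$eligible) %>%
    select("patient_id") %>%
    left_join(flags, by = "patient_id") %>%
    mutate(n_readmissions_30d = dplyr::coalesce(as.integer(.data$n_readmissions_30d), 0L),
           any_readmission_30d = .data$n_readmissions_30d >= 1L)
}

#' Classify emergency-department visits
#'
#' Counts ED visits inside follow-up, split into visits with an (unplanned,
#' unscheduled) hospital admission and visits without admission, plus
#' all-cause and COPD-related totals. Scheduled ED-to-admission events are
#' excluded from the unplanned with-admission count. An ED visit flagged
#' admitted without a matching discharge record (admit date equal to the
#' visit date) is a linkage defect: it is counted as without admission and
#' tallied in the `linkage_defects` attribute.
#'
#' @param ed_visits ED records with `patient_id`, `visit_date`,
#'   `diagnosis_code`, `admitted`, and optionally `scheduled`.
#' @inheritParams count_admissions
#' @return Tibble per eligible cohort member: `n_ed_all`, `n_ed_copd`,
#'   `n_ed_with_admission`, `n_ed_without_admission`, `any_ed_visit`.
#' @export
classify_ed_visits <- function(ed_visits, discharges, cohort,
                               case_def = copd_case_definition()) {
  check_columns(ed_visits, c("patient_id", "visit_date", "diagnosis_code",
                             "admitted"), "ed_visits")
  elig <- cohort %>% filter(.data$eligible) %>%
    select("patient_id", "followup_start", "followup_end")
  ed <- ed_visits %>%
    mutate(visit_date = as.Date(.data$visit_date)) %>%
    inner_join(elig, by = "patient_id") %>%
    filter(.data$visit_date >= .data$followup_start,
           .data$visit_date < .data$followup_end)
  if (!"scheduled" %in% names(ed)) ed$scheduled <- FALSE

  adm_keys <- discharges %>%
    mutate(admit_date = as.Date(.data$admit_date)) %>%
    distinct(.data$patient_id, .data$admit_date) %>%
    mutate(has_discharge = TRUE)
  ed <- ed %>%
    left_join(adm_keys, by = c("patient_id", "visit_date" = "admit_date")) %>%
    mutate(has_discharge = dplyr::coalesce(.data$has_discharge, FALSE))

  defect <- ed$admitted & !ed$has_discharge
  if (any(defect)) {
    warn(sprintf("%d admitted ED visit(s) had no matching discharge; counted as without admission.",
                 sum(defect)))
  }
  ed <- ed %>%
    mutate(with_admission = .data$admitted & .data$has_discharge & !.data$scheduled)

  counts <- ed %>%
    mutate(is_copd = matches_case_definition(.data$diagnosis_code, case_def)) %>%
    group_by(.data$patient_id) %>%
    summarise(n_ed_all = n(),
              n_ed_copd = sum(.data$is_copd),
              n_ed_with_admission = sum(.data$with_admission),
              .groups = "drop")
  out <- cohort %>%
    filter(.data$eligible) %>%
    select("patient_id") %>%
    left_join(counts, by = "patient_id") %>%
    mutate(across(c("n_ed_all", "n_ed_copd", "n_ed_with_admission"),
                  ~ dplyr::coalesce(as.integer(.x), 0L)),
           n_ed_without_admission = .data$n_ed_all - .data$n_ed_with_admission,
           any_ed_visit = .data$n_ed_all >= 1L)
  attr(out, "linkage_defects") <- sum(defect)
  out
}

#' In-hospital death over follow-up
#'
#' `TRUE` for patients with at least one in-window hospital episode carrying
#' a death disposition. A registry death with no hospital episode does not
#' count (the definition is discharge-based).
#'
#' @inheritParams count_admissions
#' @return Tibble: `patient_id`, `died_in_hospital`.
#' @export
in_hospital_death <- function(discharges, cohort, .episodes = NULL) {
  eps <- (.episodes %||% merge_episodes(discharges, cohort)) %>%
    filter(.data$in_window)
  flags <- eps %>%
    group_by(.data$patient_id) %>%
    summarise(died_in_hospital = any(.data$died_in_hospital), .groups = "drop")
  cohort %>%
    filter(.data$eligible) %>%
    select("patient_id") %>%
    left_join(flags, by = "patient_id") %>%
    mutate(died_in_hospital = dplyr::coalesce(.data$died_in_hospital, FALSE))
}

#' Bin a utilization count into the reporting categories
#'
#' Deterministic binning of non-negative counts into the categories used in
#' the descriptive utilization tables: `0`, `1 to 5`, `6 to 10`, `> 10`.
#'
#' @param count Integer vector of counts (>= 0).
#' @return Factor with levels `0`, `1 to 5`, `6 to 10`, `> 10`.
#' @examples
#' bin_utilization_count(c(0, 3, 5, 6, 11))
#' @export
bin_utilization_count <- function(count) {
  if (any(is.na(count)) || any(count < 0)) {
    abort("`count` must be non-negative and non-missing.")
  }
  cut(count, breaks = c(-0.5, 0.5, 5.5, 10.5, Inf),
      labels = c("0", "1 to 5", "6 to 10", "> 10"))
}

#' Per-patient unplanned-utilization summary
#'
#' Joins admission counts, 30-day readmissions, ED visit classes and
#' in-hospital death into one row per eligible cohort member.
#'
#' @inheritParams classify_ed_visits
#' @param unplanned_only Passed to [count_admissions()].
#' @return Tibble with columns `patient_id`, `n_admissions_all`,
#'   `n_admissions_copd`, `any_admission`, `n_readmissions_30d`,
#'   `any_readmission_30d`, `n_ed_all`, `n_ed_copd`, `n_ed_with_admission`,
#'   `n_ed_without_admission`, `any_ed_visit`, `died_in_hospital`.
#' @examples
#' sim <- simulate_copd_claims(sim_config(n_patients = 100, seed = 5))
#' cohort <- build_cohort(sim)
#' outcomes <- summarize_utilization(sim$discharges, sim$ed_visits, cohort)
#' @export
summarize_utilization <- function(discharges, ed_visits, cohort,
                                  case_def = copd_case_definition(),
                                  unplanned_only = FALSE) {
  eps <- merge_episodes(discharges, cohort)
  count_admissions(discharges, cohort, case_def, unplanned_only,
                   .episodes = eps) %>%
    left_join(flag_30day_readmissions(discharges, cohort, .episodes = eps),
              by = "patient_id") %>%
    left_join(classify_ed_visits(ed_visits, discharges, cohort, case_def),
              by = "patient_id") %>%
    left_join(in_hospital_death(discharges, cohort, .episodes = eps),
              by = "patient_id")
}
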