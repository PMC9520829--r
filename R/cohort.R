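#' Find each patient's COPD index date
#'
#' Scans billing claims and hospital discharges for events matching the case
#' definition and returns, per patient, the earliest qualifying event date
#' inside the recruitment window (the index date). Patients whose earliest
#' qualifying event precedes the window start have a history of COPD and are
#' flagged `prior_copd` with no index date. Patients with no qualifying
#' event anywhere are omitted.
#'
#' Discharge events qualify on the most-responsible diagnosis code and are
#' dated by admission date. Malformed (empty or missing) diagnosis codes are
#' ignored with a warning and counted in the `rejected_codes` attribute of
#' the result.
#'
#' @param claims Billing-claims tibble with columns `patient_id`,
#'   `service_date`, `diagnosis_code`.
#' @param discharges Discharge tibble with columns `patient_id`,
#'   `admit_date`, `mrd_code` (may be `NULL` or empty).
#' @param case_def A [copd_case_definition()].
#' @param recruitment_start,recruitment_end Recruitment window (dates,
#'   inclusive).
#' @return Tibble with one row per patient holding a qualifying event:
#'   `patient_id`, `index_date` (`NA` when `prior_copd`), `index_source`
#'   (`claim` or `discharge`), and `prior_copd` (logical). Attribute
#'   `rejected_codes` counts malformed diagnosis codes that were skipped.
#' @export
find_index_dates <- function(claims, discharges = NULL,
                             case_def = copd_case_definition(),
                             recruitment_start = "2005-04-01",
                             recruitment_end = "2013-03-31") {
  rs <- as_date_scalar(recruitment_start, "recruitment_start")
  re <- as_date_scalar(recruitment_end, "recruitment_end")
  if (re < rs) abort("`recruitment_end` must not precede `recruitment_start`.")
  check_columns(claims, c("patient_id", "service_date", "diagnosis_code"), "claims")

  ev_claims <- claims %>%
    transmute_events(date_col = "service_date", code_col = "diagnosis_code",
                     source = "claim")
  ev_disch <- if (!is.null(discharges) && nrow(discharges) > 0) {
    check_columns(discharges, c("patient_id", "admit_date", "mrd_code"), "discharges")
    discharges %>%
      transmute_events(date_col = "admit_date", code_col = "mrd_code",
                       source = "discharge")
  } else {
    tibble(patient_id = character(), event_date = as.Date(character()),
           code = character(), source = character())
  }
  events <- bind_rows(ev_claims, ev_disch)

  bad <- is.na(events$code) | !nzchar(events$code)
  n_rejected <- sum(bad)
  if (n_rejected > 0) {
    warn(sprintf("Ignored %d event(s) with malformed diagnosis codes.", n_rejected))
    events <- events[!bad, ]
  }

  qualifying <- events %>%
    filter(matches_case_definition(.data$code, case_def),
           .data$event_date <= re)

  firsts <- qualifying %>%
    arrange(.data$patient_id, .data$event_date) %>%
    filter(!duplicated(.data$patient_id)) %>%
    select("patient_id", first_event = "event_date")
  in_window_firsts <- qualifying %>%
    filter(.data$event_date >= rs) %>%
    arrange(.data$patient_id, .data$event_date) %>%
    filter(!duplicated(.data$patient_id)) %>%
    select("patient_id", index_date = "event_date", index_source = "source")
  out <- firsts %>%
    left_join(in_window_firsts, by = "patient_id") %>%
    mutate(prior_copd = .data$first_event < rs,
           index_date = if_else(.data$prior_copd, as.Date(NA), .data$index_date),
           index_source = if_else(.data$prior_copd, NA_character_,
                                  .data$index_source)) %>%
    select("patient_id", "index_date", "index_source", "prior_copd") %>%
    arrange(.data$patient_id)
  attr(out, "rejected_codes") <- n_rejected
  out
}

transmute_events <- function(df, date_col, code_col, source) {
  tibble(patient_id = as.character(df$patient_id),
         event_date = as.Date(df[[date_col]]),
         code = as.character(df[[code_col]]),
         source = source)
}

#' Apply cohort exclusion rules
#'
#' Screens patients holding a qualifying COPD event against the exclusion
#' rules, applied in a fixed precedence so each excluded patient carries
#' exactly one (first-matching) reason: (1) invalid patient identifier,
#' (2) not a provincial resident, (3) no health-insurance coverage at the
#' index date, (4) history of COPD before the recruitment window, then the
#' age criterion (under `min_age` at index).
#'
#' @param persons Person-registry tibble with columns `patient_id`,
#'   `birth_date`, and optionally `resident_of_province`, `coverage_start`,
#'   `coverage_end` (missing columns are treated as passing).
#' @param index_dates Output of [find_index_dates()].
#' @param min_age Minimum age (in years) at the index date.
#' @return A cohort tibble with one row per patient holding a qualifying
#'   event: `patient_id`, `index_date`, `age_at_index`, `eligible`, and
#'   `exclusion_reason` (one of `invalid_id`, `non_resident`, `no_coverage`,
#'   `prior_copd`, `under_35`, or `NA` when eligible).
#' @export
apply_exclusions <- function(persons, index_dates, min_age = 35) {
  check_columns(persons, c("patient_id", "birth_date"), "persons")
  check_columns(index_dates, c("patient_id", "index_date", "prior_copd"),
                "index_dates")

  df <- index_dates %>%
    left_join(persons, by = "patient_id") %>%
    mutate(
      age_at_index = as.numeric(.data$index_date - as.Date(.data$birth_date)) / 365.25,
      valid_id = grepl("^[A-Za-z0-9]+$", .data$patient_id),
      is_resident = if ("resident_of_province" %in% names(persons)) {
        .data$resident_of_province %in% TRUE
      } else TRUE,
      has_coverage = if (all(c("coverage_start", "coverage_end") %in% names(persons))) {
        !is.na(.data$index_date) &
          as.Date(.data$coverage_start) <= .data$index_date &
          as.Date(.data$coverage_end) >= .data$index_date
      } else !is.na(.data$index_date),
      exclusion_reason = case_when(
        !.data$valid_id ~ "invalid_id",
        !.data$is_resident ~ "non_resident",
        !.data$prior_copd & !.data$has_coverage ~ "no_coverage",
        .data$prior_copd ~ "prior_copd",
        .data$age_at_index < min_age ~ "under_35",
        TRUE ~ NA_character_
      ),
      eligible = is.na(.data$exclusion_reason)
    ) %>%
    select("patient_id", "index_date", "age_at_index", "eligible",
           "exclusion_reason")
  df
}

#' Define censored follow-up for eligible cohort members
#'
#' Sets each eligible patient's follow-up interval, a half-open interval
#' `[index_date, followup_end)`, truncated at the earliest of: the 5-year
#' anniversary of the index date, death, loss of coverage (moved out of
#' province), or the administrative study end. The censor reason reflects
#' that minimum with ties broken in the order anniversary > death > moved >
#' study end (the first two both report `end_of_window` and `death`
#' respectively; the study end also reports `end_of_window`).
#'
#' @param cohort Output of [apply_exclusions()] (only eligible rows are
#'   given follow-up; ineligible rows pass through with `NA` follow-up).
#' @param persons Person registry with `patient_id`, `death_date`, and
#'   optionally `coverage_end`.
#' @param horizon_years Follow-up horizon after index (default 5).
#' @param study_end Administrative censoring date.
#' @return The cohort tibble with added `followup_start`, `followup_end`,
#'   `censor_reason` (`end_of_window`, `death`, `moved`, or `none` for
#'   ineligible rows).
#' @export
define_followup <- function(cohort, persons, horizon_years = 5,
                            study_end = "2018-03-31") {
  se <- as_date_scalar(study_end, "study_end")
  check_columns(cohort, c("patient_id", "index_date", "eligible"), "cohort")
  check_columns(persons, c("patient_id"), "persons")

  pers <- persons %>%
    select("patient_id",
           dplyr::any_of(c("death_date", "coverage_end")))
  df <- cohort %>% left_join(pers, by = "patient_id")
  if (!"death_date" %in% names(df)) df$death_date <- as.Date(NA)
  if (!"coverage_end" %in% names(df)) df$coverage_end <- as.Date(NA)
  df$death_date <- as.Date(df$death_date)
  df$coverage_end <- as.Date(df$coverage_end)

  bad <- df$eligible & !is.na(df$death_date) & df$death_date < df$index_date
  if (any(bad)) {
    abort(sprintf("data-integrity error: death before index date for %d patient(s), e.g. %s.",
                  sum(bad), df$patient_id[which(bad)[1]]))
  }

  far <- as.Date("9999-12-31")
  anniversary <- add_years(df$index_date, as.integer(horizon_years))
  cand <- cbind(as.numeric(anniversary),
                as.numeric(if_else(is.na(df$death_date), far, df$death_date)),
                as.numeric(if_else(is.na(df$coverage_end), far, df$coverage_end)),
                as.numeric(se))
  fu_end <- as.Date(pmin(cand[, 1], cand[, 2], cand[, 3], cand[, 4]),
                    origin = "1970-01-01")
  # tie precedence: anniversary, death, moved, study end
  reason <- case_when(
    !df$eligible ~ "none",
    cand[, 1] <= cand[, 2] & cand[, 1] <= cand[, 3] & cand[, 1] <= cand[, 4] ~ "end_of_window",
    cand[, 2] <= cand[, 3] & cand[, 2] <= cand[, 4] ~ "death",
    cand[, 3] <= cand[, 4] ~ "moved",
    TRUE ~ "end_of_window"
  )
  df %>%
    mutate(followup_start = if_else(.data$eligible, .data$index_date, as.Date(NA)),
           followup_end = if_else(.data$eligible, fu_end, as.Date(NA)),
           censor_reason = reason) %>%
    select(-"death_date", -"coverage_end")
}

#' Build the analysis cohort from linked tables
#'
#' One-stop wrapper: [find_index_dates()] then [apply_exclusions()] then
#' [define_followup()].
#'
#' @param tables A named list with `persons`, `claims` and optionally
#'   `discharges` tibbles (for example a `coc_sim`).
#' @inheritParams find_index_dates
#' @inheritParams apply_exclusions
#' @inheritParams define_followup
#' @return Cohort tibble: one row per patient with a qualifying event,
#'   carrying `index_date`, `age_at_index`, `eligible`, `exclusion_reason`,
#'   `followup_start`, `followup_end`, `censor_reason`.
#' @examples
#' sim <- simulate_copd_claims(sim_config(n_patients = 100, seed = 3))
#' cohort <- build_cohort(sim)
#' dplyr::count(cohort, eligible, exclusion_reason)
#' @export
build_cohort <- function(tables,
                         case_def = copd_case_definition(),
                         recruitment_start = "2005-04-01",
                         recruitment_end = "2013-03-31",
                         min_age = 35,
                         horizon_years = 5,
                         study_end = "2018-03-31") {
  idx <- find_index_dates(tables$claims, tables$discharges, case_def,
                          recruitment_start, recruitment_end)
  apply_exclusions(tables$persons, idx, min_age = min_age) %>%
    define_followup(tables$persons, horizon_years = horizon_years,
                    study_end = study_end)
}
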