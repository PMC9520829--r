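#' Continuity-of-care indices
#'
#' The three claim-based continuity indices over one patient's ordered
#' outpatient visit sequence, written in terms of the total visit count
#' \eqn{N}, per-provider visit counts \eqn{n_j}, and the chronological
#' provider sequence:
#'
#' * **UPC** (usual provider of care): \eqn{\max_j n_j / N}, the share of
#'   visits made to the most-visited provider. Defined for \eqn{N \ge 1}.
#' * **COC** (Bice-Boxerman concentration of care):
#'   \eqn{(\sum_j n_j^2 - N) / (N (N - 1))} — the probability that two
#'   distinct visits drawn without replacement share a provider. 0 when
#'   every visit is to a different provider, 1 when all visits are to the
#'   same provider. Defined for \eqn{N \ge 2}.
#' * **SECON** (sequential continuity): the fraction of adjacent visit
#'   pairs made to the same provider,
#'   \eqn{\sum_{i<N} 1[p_i = p_{i+1}] / (N-1)}. 0 for strict alternation
#'   between two providers, 1 for a constant provider. Defined for
#'   \eqn{N \ge 2}; order matters.
#'
#' `upc_index()` and `coc_index()` accept either a provider label vector or
#' a numeric vector of per-provider counts; `secon_index()` requires the
#' ordered label sequence.
#'
#' @param x Provider labels in visit order (character/factor), or for
#'   `upc_index()`/`coc_index()` a numeric vector of per-provider counts.
#' @param providers Ordered provider label vector.
#' @return A single number in \[0, 1\].
#' @examples
#' upc_index(c("A", "A", "B"))      # 2/3
#' coc_index(c(2, 2))               # counts (2,2) -> 1/3
#' secon_index(c("A", "A", "B", "B"))  # 2/3
#' @name continuity_indices
NULL

provider_counts <- function(x) {
  if (is.numeric(x)) {
    if (any(x < 0) || any(x != round(x))) {
      abort("numeric input must be non-negative integer visit counts.")
    }
    x[x > 0]
  } else {
    as.numeric(table(as.character(x)))
  }
}

#' @rdname continuity_indices
#' @export
upc_index <- function(x) {
  n_j <- provider_counts(x)
  N <- sum(n_j)
  if (N < 1) abort("UPC is undefined for an empty visit sequence (N = 0).")
  max(n_j) / N
}

#' @rdname continuity_indices
#' @export
coc_index <- function(x) {
  n_j <- provider_counts(x)
  N <- sum(n_j)
  if (N < 2) abort("COC is undefined for fewer than 2 visits.")
  (sum(n_j^2) - N) / (N * (N - 1))
}

#' @rdname continuity_indices
#' @export
secon_index <- function(providers) {
  if (is.numeric(providers)) {
    abort("SECON needs the ordered provider sequence, not counts.")
  }
  providers <- as.character(providers)
  N <- length(providers)
  if (N < 2) abort("SECON is undefined for fewer than 2 visits.")
  mean(providers[-1] == providers[-N])
}

#' Build per-patient outpatient visit sequences
#'
#' Restricts billing claims to outpatient visits within each cohort
#' member's follow-up interval `[followup_start, followup_end)`, collapses
#' multiple same-day claims to the same physician into one visit, and
#' returns one row per visit in stable chronological order (date, then
#' physician id for same-day visits to different physicians). Claims for
#' patients absent from the eligible cohort are dropped (their count is kept
#' in the `dropped_claims` attribute).
#'
#' Patients with 5 or fewer visits are flagged ineligible for continuity
#' index computation (`index_eligible = FALSE` in the summary attributes of
#' downstream profiles).
#'
#' @param claims Billing claims with `patient_id`, `physician_id`,
#'   `specialty`, `service_date` and optionally `setting` (non-`outpatient`
#'   rows are dropped when present).
#' @param cohort Cohort tibble from [build_cohort()] /
#'   [define_followup()]; only eligible rows are used.
#' @return Tibble of visits: `patient_id`, `service_date`, `physician_id`,
#'   `specialty_group`, `visit_rank`, with attribute `dropped_claims`.
#' @export
build_visit_sequences <- function(claims, cohort) {
  check_columns(claims, c("patient_id", "physician_id", "specialty",
                          "service_date"), "claims")
  check_columns(cohort, c("patient_id", "eligible", "followup_start",
                          "followup_end"), "cohort")
  elig <- cohort %>% filter(.data$eligible)

  cl <- claims
  if ("setting" %in% names(cl)) cl <- cl %>% filter(.data$setting == "outpatient")
  cl <- cl %>%
    filter(.data$specialty %in% c("FP", "RESP")) %>%
    mutate(service_date = as.Date(.data$service_date))

  n_before <- nrow(cl)
  joined <- cl %>%
    inner_join(elig %>% select("patient_id", "followup_start", "followup_end"),
               by = "patient_id") %>%
    filter(.data$service_date >= .data$followup_start,
           .data$service_date < .data$followup_end)
  dropped <- n_before - nrow(joined) # out-of-window or non-cohort claims

  visits <- joined %>%
    distinct(.data$patient_id, .data$service_date, .data$physician_id,
             .keep_all = TRUE) %>%
    arrange(.data$patient_id, .data$service_date, .data$physician_id) %>%
    group_by(.data$patient_id) %>%
    mutate(visit_rank = row_number()) %>%
    ungroup() %>%
    transmute(.data$patient_id, .data$service_date, .data$physician_id,
              specialty_group = if_else(.data$specialty == "FP", "FP", "SP"),
              .data$visit_rank)
  attr(visits, "dropped_claims") <- dropped
  visits
}

#' Predominant provider group of a visit sequence
#'
#' Classifies each patient as FP- or specialist-anchored by which specialty
#' group received strictly more of their outpatient visits; an exact tie is
#' assigned to FP (the system's default attachment point).
#'
#' @param visits Visit tibble from [build_visit_sequences()].
#' @return Tibble: `patient_id`, `predominant_group` (`"FP"`/`"SP"`),
#'   `fp_visit_share`.
#' @export
classify_predominant_provider <- function(visits) {
  check_columns(visits, c("patient_id", "specialty_group"), "visits")
  visits %>%
    group_by(.data$patient_id) %>%
    summarise(fp_visit_share = mean(.data$specialty_group == "FP"),
              .groups = "drop") %>%
    mutate(predominant_group = if_else(.data$fp_visit_share >= 0.5, "FP", "SP")) %>%
    select("patient_id", "predominant_group", "fp_visit_share")
}

#' Great-circle distance in kilometres
#'
#' Haversine distance between two latitude/longitude points on a sphere of
#' radius 6371 km. Vectorized over all arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance(s) in kilometres.
#' @examples
#' distance_km(0, 0, 1, 0) # about 111.19
#' @export
distance_km <- function(lat1, lon1, lat2, lon2) {
  for (nm in c("lat1", "lat2")) {
    v <- get(nm)
    if (any(!is.na(v) & abs(v) > 90)) {
      abort(sprintf("invalid coordinate: `%s` outside [-90, 90].", nm))
    }
  }
  for (nm in c("lon1", "lon2")) {
    v <- get(nm)
    if (any(!is.na(v) & abs(v) > 180)) {
      abort(sprintf("invalid coordinate: `%s` outside [-180, 180].", nm))
    }
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371)
}

#' Dichotomize the concentration-of-care index at the cohort median
#'
#' Splits patients into low/high COC groups at the median of the COC score
#' over patients eligible for index computation (more than 5 visits).
#' Scores at or below the median are `low`, above it `high`; patients with
#' 5 or fewer visits are `not_assessed`.
#'
#' @param profiles Tibble with columns `coc` and `n_visits`.
#' @param min_visits Visit-count threshold; patients with `n_visits <=
#'   min_visits` are not assessed (default 5).
#' @return `profiles` with an added `coci_category` column (factor with
#'   levels `high`, `low`, `not_assessed`) and attribute `coci_median`.
#' @export
dichotomize_coci <- function(profiles, min_visits = 5L) {
  check_columns(profiles, c("coc", "n_visits"), "profiles")
  assessed <- profiles$n_visits > min_visits & !is.na(profiles$coc)
  if (!any(assessed)) {
    abort("No patients eligible for the COCI median split (all have too few visits).")
  }
  med <- median(profiles$coc[assessed])
  profiles$coci_category <- factor(
    dplyr::case_when(!assessed ~ "not_assessed",
                     profiles$coc <= med ~ "low",
                     TRUE ~ "high"),
    levels = c("high", "low", "not_assessed")
  )
  attr(profiles, "coci_median") <- med
  profiles
}

#' Per-patient continuity profiles
#'
#' Computes the full continuity profile for every eligible cohort member:
#' visit counts, the UPC / COC / SECON indices (over outpatient FP and
#' respiratory-specialist visits in follow-up), the predominant provider
#' group, the distance from the patient's residence to their usual
#' provider's office (when geolocations are supplied), and the median-cut
#' COCI category.
#'
#' The usual provider is the physician with the most visits; ties go to the
#' physician seen earliest. Indices are reported as `NA` for patients with
#' 5 or fewer visits, whose `coci_category` is `not_assessed`.
#'
#' @param claims,cohort Passed to [build_visit_sequences()].
#' @param persons Optional person registry with `residence_lat`,
#'   `residence_lon` for the distance computation.
#' @param physicians Optional physician registry with `physician_id`,
#'   `office_lat`, `office_lon`.
#' @param min_visits Threshold below which continuity is not assessed.
#' @return Tibble with one row per eligible cohort member: `patient_id`,
#'   `n_visits`, `k_providers`, `upc`, `coc`, `secon`, `predominant_group`,
#'   `fp_visit_share`, `usual_physician_id`, `distance_km`,
#'   `coci_category`. Attribute `coci_median` holds the split point.
#' @examples
#' sim <- simulate_copd_claims(sim_config(n_patients = 120, seed = 11))
#' cohort <- build_cohort(sim)
#' profiles <- compute_continuity(sim$claims, cohort, sim$persons, sim$physicians)
#' head(profiles)
#' @export
compute_continuity <- function(claims, cohort, persons = NULL,
                               physicians = NULL, min_visits = 5L) {
  visits <- build_visit_sequences(claims, cohort)

  # visits arrive sorted by (patient, date, physician); the first occurrence
  # of each patient-physician pair is that pair's earliest visit
  pair_key <- paste(visits$patient_id, visits$physician_id, sep = "\r")
  firsts <- visits[!duplicated(pair_key), c("patient_id", "physician_id",
                                            "service_date")]
  per_provider <- visits %>%
    count(.data$patient_id, .data$physician_id, name = "n_j") %>%
    left_join(firsts %>% rename(first_visit = "service_date"),
              by = c("patient_id", "physician_id"))

  concentration <- per_provider %>%
    group_by(.data$patient_id) %>%
    summarise(n_visits = sum(.data$n_j),
              k_providers = n(),
              max_nj = max(.data$n_j),
              sum_sq = sum(.data$n_j^2),
              .groups = "drop") %>%
    mutate(upc = .data$max_nj / .data$n_visits,
           coc = if_else(.data$n_visits >= 2,
                         (.data$sum_sq - .data$n_visits) /
                           (.data$n_visits * (.data$n_visits - 1)),
                         NA_real_)) %>%
    select(-"max_nj", -"sum_sq")
  usual <- per_provider %>%
    arrange(.data$patient_id, dplyr::desc(.data$n_j), .data$first_visit,
            .data$physician_id) %>%
    filter(!duplicated(.data$patient_id)) %>%
    select("patient_id", usual_physician_id = "physician_id")
  concentration <- concentration %>% left_join(usual, by = "patient_id")

  ordered <- visits %>% arrange(.data$patient_id, .data$visit_rank)
  m <- nrow(ordered)
  same_patient <- c(FALSE, ordered$patient_id[-m] == ordered$patient_id[-1])
  same_provider <- c(FALSE, ordered$physician_id[-m] == ordered$physician_id[-1])
  sequential <- tibble(patient_id = ordered$patient_id[same_patient],
                       same = same_provider[same_patient]) %>%
    group_by(.data$patient_id) %>%
    summarise(secon = mean(.data$same), .groups = "drop")

  profiles <- concentration %>%
    left_join(sequential, by = "patient_id") %>%
    left_join(classify_predominant_provider(visits), by = "patient_id")

  profiles <- profiles %>%
    mutate(across(c("upc", "coc", "secon"),
                  ~ if_else(.data$n_visits > min_visits, .x, NA_real_)))

  if (!is.null(persons) && !is.null(physicians) &&
      all(c("residence_lat", "residence_lon") %in% names(persons)) &&
      all(c("office_lat", "office_lon") %in% names(physicians))) {
    profiles <- profiles %>%
      left_join(persons %>% select("patient_id", "residence_lat", "residence_lon"),
                by = "patient_id") %>%
      left_join(physicians %>%
                  select(usual_physician_id = "physician_id",
                         "office_lat", "office_lon"),
                by = "usual_physician_id") %>%
      mutate(distance_km = distance_km(.data$residence_lat, .data$residence_lon,
                                       .data$office_lat, .data$office_lon)) %>%
      select(-"residence_lat", -"residence_lon", -"office_lat", -"office_lon")
  } else {
    profiles$distance_km <- NA_real_
  }

  dichotomize_coci(profiles, min_visits = min_visits)
}
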