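#' Allocate a patient's visits across their provider pool
#'
#' Draws an ordered provider sequence for one patient under a symmetric
#' Dirichlet-multinomial: provider weights are drawn from a symmetric
#' Dirichlet with concentration `dispersion_alpha`, then each visit picks a
#' provider independently with those weights. Small `dispersion_alpha`
#' concentrates all visits on one (random) provider; large values spread
#' visits evenly, so the expected concentration-of-care index decreases
#' monotonically in `dispersion_alpha` from 1 towards `1/length(pool)`.
#'
#' Randomness comes from R's global RNG stream; fix it with [set.seed()] for
#' reproducible sequences.
#'
#' @param total_visits Number of visits to allocate (>= 1).
#' @param pool Vector of provider labels (non-empty).
#' @param dispersion_alpha Positive Dirichlet concentration parameter.
#' @return A vector of `total_visits` provider labels drawn from `pool`,
#'   in chronological order.
#' @examples
#' set.seed(1)
#' allocate_visits(7, c("A", "B", "C"), dispersion_alpha = 0.2)
#' @export
allocate_visits <- function(total_visits, pool, dispersion_alpha) {
  check_positive_scalar(total_visits, "total_visits", integer = TRUE)
  if (length(pool) == 0L) abort("`pool` must be non-empty.")
  check_positive_scalar(dispersion_alpha, "dispersion_alpha")
  pool[draw_slots(total_visits, length(pool), dispersion_alpha)]
}

draw_slots <- function(total_visits, K, dispersion_alpha) {
  if (K == 1L) return(rep(1L, total_visits))
  w <- rgamma(K, shape = dispersion_alpha)
  if (!any(w > 0)) {
    # Dirichlet weights underflow for very small alpha: the limit puts all
    # mass on a single uniformly chosen provider
    w[sample.int(K, 1L)] <- 1
  }
  sample.int(K, total_visits, replace = TRUE, prob = w)
}

add_years <- function(dates, k) {
  lt <- as.POSIXlt(dates)
  lt$year <- lt$year + k
  as.Date(lt)
}

# benign (non-COPD) outpatient / discharge diagnosis codes
.benign_codes <- c("J06", "I10", "E11", "Z00", "M54", "K21", "N39")

#' Generate linked synthetic claims tables with known continuity truth
#'
#' Simulates a linked set of administrative-claims-style tables for a cohort
#' of newly diagnosed COPD patients: a person registry, a physician registry,
#' outpatient billing claims, hospital discharge abstracts and emergency-
#' department records, together with a ground-truth table holding each
#' patient's realized continuity indices, planted low-continuity group and
#' outcome probability.
#'
#' Each patient receives an index COPD billing claim on a random date in the
#' recruitment window, a heavy-tailed number of follow-up outpatient visits
#' on distinct days allocated across a personal provider pool by
#' [allocate_visits()], and unplanned utilization drawn from logistic /
#' Poisson models whose low-continuity terms are set in the configuration.
#' The low-continuity group in the truth table is the dichotomization of the
#' realized concentration-of-care index at the median over patients expected
#' to reach the analysis set (more than 5 visits, no planted exclusion), so
#' a downstream refit against the truth design recovers the planted odds
#' ratio.
#'
#' All randomness is governed by `config$seed`: the root seed spawns a fixed
#' sub-seed per generation stage, so identical configurations reproduce
#' identical tables.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `coc_sim`: a list of tibbles `persons`,
#'   `physicians`, `claims`, `discharges`, `ed_visits`, `truth`, plus the
#'   `config` used. All dates are `Date` columns; [write_claims_csv()]
#'   serializes them as ISO-8601.
#' @examples
#' sim <- simulate_copd_claims(sim_config(n_patients = 50, seed = 7))
#' sim$truth
#' @export
simulate_copd_claims <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    abort("configuration error: `config` must be built by sim_config().")
  }
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 3L)

  n <- config$n_patients
  persons <- sim_persons(config, stage_seeds[1])
  net <- sim_visits(config, persons, stage_seeds[2])
  out <- sim_utilization(config, persons, net$truth, stage_seeds[3])

  truth <- net$truth %>%
    left_join(out$truth_outcomes, by = "patient_id")

  structure(
    list(persons = persons %>% select(-"index_date_true", -"followup_days",
                                      -"age_at_index_true"),
         physicians = net$physicians,
         claims = net$claims,
         discharges = out$discharges,
         ed_visits = out$ed_visits,
         truth = truth,
         config = config),
    class = "coc_sim"
  )
}

#' @export
print.coc_sim <- function(x, ...) {
  cat("<coc_sim> synthetic linked claims\n")
  cat(sprintf("  %d persons | %d physicians | %d claims | %d discharges | %d ED visits\n",
              nrow(x$persons), nrow(x$physicians), nrow(x$claims),
              nrow(x$discharges), nrow(x$ed_visits)))
  cat(sprintf("  planted low-COCI admission OR %.3f, seed %d\n",
              exp(x$config$outcome_coefficients[["low_coci"]]), x$config$seed))
  invisible(x)
}

sim_persons <- function(config, seed) {
  set.seed(seed)
  n <- config$n_patients
  ex <- config$exclusion_rates

  id <- sprintf("P%06d", seq_len(n))
  invalid <- runif(n) < ex[["invalid_id"]]
  id[invalid] <- sprintf("X-%05d!", which(invalid))

  sex <- if_else(runif(n) < 0.5, "F", "M")
  # age at index: truncated normal, mean 61.5 sd 14.6, support [30, 100]
  lo <- stats::pnorm(30, 61.5, 14.6); hi <- stats::pnorm(100, 61.5, 14.6)
  age <- stats::qnorm(runif(n, lo, hi), 61.5, 14.6)

  window_days <- as.integer(config$recruitment_end - config$recruitment_start)
  index_date <- config$recruitment_start + floor(runif(n) * (window_days + 1))
  birth_date <- index_date - round(age * 365.25)

  rates <- config$censoring_rates
  death_days <- if (rates[["death"]] > 0) {
    ceiling(rexp(n, rates[["death"]] / 365.25))
  } else rep(Inf, n)
  death_date <- index_date + pmin(death_days, 1e7)
  death_date[death_days > as.numeric(config$study_end - index_date)] <- NA

  move_days <- if (rates[["move"]] > 0) {
    ceiling(rexp(n, rates[["move"]] / 365.25))
  } else rep(Inf, n)
  coverage_end <- index_date + pmin(move_days, 36525)
  no_cov <- runif(n) < ex[["no_coverage"]]
  coverage_end[no_cov] <- index_date[no_cov] - sample(30:365, sum(no_cov), replace = TRUE)

  non_resident <- runif(n) < ex[["non_resident"]]
  prior_copd <- runif(n) < ex[["prior_copd"]]

  marg <- matrix(sample(1:5, 4L * n, replace = TRUE), ncol = 4L)

  fu_end <- pmin(add_years(index_date, 5L),
                 if_else(is.na(death_date), as.Date("9999-01-01"), death_date),
                 coverage_end, config$study_end)
  followup_days <- pmax(1L, as.integer(fu_end - index_date))

  tibble(
    patient_id = id,
    birth_date = birth_date,
    sex = sex,
    death_date = death_date,
    residence_lat = runif(n, 42.5, 46.5),
    residence_lon = runif(n, -83, -75),
    income_quintile = sample(1:5, n, replace = TRUE,
                             prob = c(0.23, 0.22, 0.20, 0.19, 0.17)),
    marg_dependency = marg[, 1], marg_deprivation = marg[, 2],
    marg_ethnic = marg[, 3], marg_instability = marg[, 4],
    marg_composite = rowMeans(marg),
    rural = runif(n) < 0.155,
    adg_score = 1L + rpois(n, 5.5),
    resident_of_province = !non_resident,
    coverage_start = birth_date,
    coverage_end = coverage_end,
    planted_prior_copd = prior_copd,
    index_date_true = index_date,
    followup_days = followup_days,
    age_at_index_true = age
  )
}

sim_visits <- function(config, persons, seed) {
  set.seed(seed)
  n <- nrow(persons)
  K <- config$provider_pool_size

  n_fp <- max(30L, ceiling(n / 40))
  n_sp <- max(10L, ceiling(n / 200))
  physicians <- tibble(
    physician_id = c(sprintf("FP%05d", seq_len(n_fp)),
                     sprintf("SP%04d", seq_len(n_sp))),
    specialty = rep(c("FP", "RESP"), c(n_fp, n_sp)),
    office_lat = runif(n_fp + n_sp, 42.5, 46.5),
    office_lon = runif(n_fp + n_sp, -83, -75)
  )
  fp_ids <- physicians$physician_id[physicians$specialty == "FP"]
  sp_ids <- physicians$physician_id[physicians$specialty == "RESP"]

  sp_type <- runif(n) < config$p_specialist_predominant
  # visit counts: 1 (index claim) + negative binomial tail
  n_visits <- 1L + rnbinom(n, size = config$visit_size, mu = config$mean_visits - 1)
  n_visits <- pmin(n_visits, persons$followup_days)

  phys_out <- vector("list", n)
  spec_out <- vector("list", n)
  day_out <- vector("list", n)
  upc_v <- coc_v <- secon_v <- numeric(n)
  k_v <- integer(n)
  predom <- character(n)

  alpha <- config$dispersion_alpha
  fu_days <- persons$followup_days
  spec_labels <- c("FP", "RESP")

  for (i in seq_len(n)) {
    Ni <- n_visits[i]
    slots <- draw_slots(Ni, K, alpha)
    cnt <- tabulate(slots, K)
    usual_slot <- which.max(cnt)
    # specialty by pool slot; the busiest slot carries the patient's
    # predominant provider type
    p_sp_other <- if (sp_type[i]) 0.5 else 0.06
    slot_is_sp <- runif(K) < p_sp_other
    slot_is_sp[usual_slot] <- sp_type[i]
    n_sp_slots <- sum(slot_is_sp)
    slot_ids <- character(K)
    if (n_sp_slots > 0) slot_ids[slot_is_sp] <- sample(sp_ids, n_sp_slots)
    if (n_sp_slots < K) slot_ids[!slot_is_sp] <- sample(fp_ids, K - n_sp_slots)

    fd <- fu_days[i]
    days <- if (Ni > 1L) c(0L, sort(sample.int(fd - 1L, Ni - 1L))) else 0L

    upc_v[i] <- max(cnt) / Ni
    coc_v[i] <- if (Ni >= 2L) (sum(cnt^2) - Ni) / (Ni * (Ni - 1)) else NA_real_
    secon_v[i] <- if (Ni >= 2L) mean(slots[-1] == slots[-Ni]) else NA_real_
    k_v[i] <- sum(cnt > 0L)
    predom[i] <- if (sum(cnt[slot_is_sp]) > Ni / 2) "SP" else "FP"

    phys_out[[i]] <- slot_ids[slots]
    spec_out[[i]] <- spec_labels[slot_is_sp[slots] + 1L]
    day_out[[i]] <- days
  }

  claims <- tibble(
    patient_id = rep(persons$patient_id, n_visits),
    physician_id = unlist(phys_out),
    specialty = unlist(spec_out),
    service_date = rep(persons$index_date_true, n_visits) + unlist(day_out),
    setting = "outpatient"
  )
  # first visit of each patient is the index COPD claim; later visits are
  # mostly non-COPD
  first_row <- !duplicated(claims$patient_id)
  m <- nrow(claims)
  claims$diagnosis_code <- sample(.benign_codes, m, replace = TRUE)
  copd_later <- !first_row & runif(m) < 0.10
  claims$diagnosis_code[copd_later] <- sample(c("491", "492", "496", "J44"),
                                              sum(copd_later), replace = TRUE)
  claims$diagnosis_code[first_row] <-
    sample(c("491", "492", "496", "J41", "J42", "J43", "J44"), n, replace = TRUE)

  # a sprinkle of non-outpatient claims the pipeline must filter out
  n_other <- rpois(n, 0.3)
  keep <- n_other > 0
  if (any(keep)) {
    other <- tibble(
      patient_id = rep(persons$patient_id[keep], n_other[keep]),
      physician_id = sample(physicians$physician_id, sum(n_other), replace = TRUE),
      specialty = "FP",
      service_date = rep(persons$index_date_true[keep], n_other[keep]) +
        sample.int(300L, sum(n_other), replace = TRUE),
      setting = "other",
      diagnosis_code = sample(.benign_codes, sum(n_other), replace = TRUE)
    )
    claims <- bind_rows(claims, other)
  }

  # planted pre-window COPD claims (history of COPD -> excluded downstream)
  pri <- which(persons$planted_prior_copd)
  if (length(pri)) {
    prior <- tibble(
      patient_id = persons$patient_id[pri],
      physician_id = sample(fp_ids, length(pri), replace = TRUE),
      specialty = "FP",
      service_date = config$recruitment_start -
        sample(30:1095, length(pri), replace = TRUE),
      setting = "outpatient",
      diagnosis_code = sample(c("491", "492", "496", "J44"), length(pri),
                              replace = TRUE)
    )
    claims <- bind_rows(claims, prior)
  }
  claims <- claims %>% arrange(.data$patient_id, .data$service_date,
                               .data$physician_id)

  truth <- tibble(
    patient_id = persons$patient_id,
    index_date = persons$index_date_true,
    predominant_type = predom,
    n_visits = n_visits,
    k_providers = k_v,
    true_upc = upc_v, true_coc = coc_v, true_secon = secon_v,
    age_at_index = persons$age_at_index_true
  )
  expected_in_analysis <- n_visits > 5L &
    !persons$planted_prior_copd &
    persons$resident_of_province &
    grepl("^P[0-9]+$", persons$patient_id) &
    persons$coverage_end >= persons$index_date_true &
    persons$age_at_index_true >= 35
  med <- median(truth$true_coc[expected_in_analysis])
  truth$true_low_coci <- truth$true_coc <= med
  truth$expected_in_analysis <- expected_in_analysis

  list(claims = claims, physicians = physicians, truth = truth)
}

sim_utilization <- function(config, persons, truth, seed) {
  set.seed(seed)
  n <- nrow(persons)
  b <- config$outcome_coefficients
  low <- as.numeric(truth$true_low_coci)
  low[is.na(low)] <- 0

  eta <- b[["intercept"]] +
    b[["low_coci"]] * low +
    b[["age10"]] * (persons$age_at_index_true - 60) / 10 +
    b[["male"]] * (persons$sex == "M") +
    b[["adg"]] * (persons$adg_score - 6) +
    b[["marg"]] * (persons$marg_composite - 3) +
    b[["rural"]] * persons$rural
  p_adm <- plogis(eta)
  any_adm <- runif(n) < p_adm

  am <- config$admission_count_model
  n_adm <- integer(n)
  n_adm[any_adm] <- 1L + rpois(sum(any_adm),
                               exp(am[["log_rate"]] + am[["low_coci"]] * low[any_adm]))

  # expand to one row per admission, chained within patient:
  # admit_k = index + gap_1 + sum_{j<k} (los_j + gap_{j+1})
  idx <- rep(seq_len(n), n_adm)
  if (length(idx)) {
    ord_k <- sequence(n_adm[n_adm > 0])
    fd <- persons$followup_days[idx]
    los <- 1L + rpois(length(idx), 5)

    rm <- config$readmission_model
    p_readmit <- plogis(rm[["base_logit"]] + rm[["low_coci"]] * low[idx])
    is_readmit <- ord_k > 1L & runif(length(idx)) < p_readmit
    gap <- integer(length(idx))
    gap[ord_k == 1L] <- floor(runif(sum(ord_k == 1L)) * fd[ord_k == 1L])
    later <- ord_k > 1L
    gap[later & is_readmit] <- sample.int(30L, sum(later & is_readmit), replace = TRUE)
    slow <- later & !is_readmit
    gap[slow] <- 31L + rpois(sum(slow), 60)

    prev_los <- c(0L, los[-length(los)])
    prev_los[ord_k == 1L] <- 0L
    admit_offset <- cumsum_by(gap + prev_los, idx)
    admit_date <- persons$index_date_true[idx] + admit_offset
    in_window <- admit_offset < persons$followup_days[idx]

    category <- rep("emergent", length(idx))
    free <- !is_readmit  # planted readmissions are always emergent
    category[free] <- sample(c("emergent", "elective", "transfer"),
                             sum(free), replace = TRUE,
                             prob = c(0.88, 0.10, 0.02))

    discharge_date <- admit_date + los
    died <- !is.na(persons$death_date[idx]) &
      persons$death_date[idx] >= admit_date &
      persons$death_date[idx] <= discharge_date
    discharge_date[died] <- persons$death_date[idx][died]

    mrd_copd <- runif(length(idx)) < 0.35
    mrd <- sample(.benign_codes, length(idx), replace = TRUE)
    mrd[mrd_copd] <- sample(c("491", "492", "496", "J44"), sum(mrd_copd),
                            replace = TRUE)

    discharges <- tibble(
      patient_id = persons$patient_id[idx],
      admit_date = admit_date,
      discharge_date = discharge_date,
      mrd_code = mrd,
      other_codes = sample(.benign_codes, length(idx), replace = TRUE),
      admission_category = category,
      died_in_hospital = died
    )[in_window, ]

    truth_readmit <- tibble(patient_id = persons$patient_id[idx],
                            readmit = is_readmit & in_window) %>%
      group_by(.data$patient_id) %>%
      summarise(n_readmissions_30d = sum(.data$readmit), .groups = "drop")
  } else {
    discharges <- tibble(patient_id = character(), admit_date = as.Date(character()),
                         discharge_date = as.Date(character()), mrd_code = character(),
                         other_codes = character(), admission_category = character(),
                         died_in_hospital = logical())
    truth_readmit <- tibble(patient_id = character(), n_readmissions_30d = integer())
  }

  # ED visits attached to emergent admissions (linkage invariant)
  emerg <- discharges %>% filter(.data$admission_category == "emergent")
  ed_adm <- tibble(
    patient_id = emerg$patient_id,
    visit_date = emerg$admit_date,
    diagnosis_code = if_else(runif(nrow(emerg)) < 0.7, emerg$mrd_code,
                             sample(.benign_codes, nrow(emerg), replace = TRUE)),
    admitted = TRUE,
    scheduled = runif(nrow(emerg)) < 0.02
  )

  em <- config$ed_model
  n_ed0 <- rpois(n, exp(em[["log_rate"]] + em[["low_coci"]] * low))
  idx0 <- rep(seq_len(n), n_ed0)
  ed_free <- tibble(
    patient_id = persons$patient_id[idx0],
    visit_date = persons$index_date_true[idx0] +
      floor(runif(length(idx0)) * persons$followup_days[idx0]),
    diagnosis_code = {
      m0 <- length(idx0)
      dx <- sample(.benign_codes, m0, replace = TRUE)
      cop <- runif(m0) < 0.2
      dx[cop] <- sample(c("491", "492", "496", "J44"), sum(cop), replace = TRUE)
      dx
    },
    admitted = FALSE,
    scheduled = FALSE
  )
  ed_visits <- bind_rows(ed_adm, ed_free) %>%
    arrange(.data$patient_id, .data$visit_date)

  truth_outcomes <- tibble(
    patient_id = persons$patient_id,
    p_admission = p_adm,
    any_admission = any_adm,
    n_admissions = n_adm
  ) %>%
    left_join(truth_readmit, by = "patient_id") %>%
    mutate(n_readmissions_30d = dplyr::coalesce(.data$n_readmissions_30d, 0L),
           n_ed_without_admission = n_ed0)

  list(discharges = discharges, ed_visits = ed_visits,
       truth_outcomes = truth_outcomes)
}

#' Write / read the synthetic tables as CSV
#'
#' `write_claims_csv()` serializes the five linked tables plus the truth
#' table to a directory (`persons.csv`, `physicians.csv`, `claims.csv`,
#' `discharges.csv`, `ed_visits.csv`, `truth.csv`), all dates ISO-8601.
#' `read_claims_tables()` reads them back into a list of tibbles.
#'
#' @param sim A `coc_sim` object from [simulate_copd_claims()].
#' @param dir Output directory (created if needed).
#' @return `write_claims_csv()` returns `dir` invisibly;
#'   `read_claims_tables()` returns a named list of tibbles.
#' @export
write_claims_csv <- function(sim, dir) {
  stopifnot(inherits(sim, "coc_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (nm in c("persons", "physicians", "claims", "discharges", "ed_visits", "truth")) {
    readr::write_csv(sim[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' @rdname write_claims_csv
#' @export
read_claims_tables <- function(dir) {
  nms <- c("persons", "physicians", "claims", "discharges", "ed_visits", "truth")
  out <- lapply(nms, function(nm) {
    readr::read_csv(file.path(dir, paste0(nm, ".csv")), show_col_types = FALSE)
  })
  setNames(out, nms)
}
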