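#' Configuration for the synthetic linked-claims generator
#'
#' Builds and validates the parameter set for [simulate_copd_claims()]. The
#' defaults emulate the visit, continuity and utilization structure of a
#' large provincial COPD inception cohort: 5-year outpatient visit counts
#' follow a heavy-tailed negative binomial (about 70% of patients exceed 20
#' visits), visits spread over a personal provider pool under a symmetric
#' Dirichlet-multinomial (mean concentration-of-care index about 0.51), and
#' unplanned utilization follows a logistic outcome model with a planted
#' low-continuity effect (default odds ratio 2.25 on any admission).
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer root seed. The generator derives independent
#'   sub-seeds per stage, so the same config and seed reproduce identical
#'   tables.
#' @param recruitment_start,recruitment_end Recruitment window for the
#'   first (index) COPD diagnosis date.
#' @param study_end Administrative end of follow-up.
#' @param mean_visits Mean of the negative-binomial 5-year outpatient visit
#'   count (the realized count is `1 + NegBin(visit_size, mean_visits - 1)`
#'   so every patient has at least the index visit).
#' @param visit_size Negative-binomial size (inverse dispersion) of the
#'   visit count; smaller values give a heavier right tail.
#' @param dispersion_alpha Concentration parameter of the symmetric
#'   Dirichlet governing how a patient's visits spread across their provider
#'   pool. Small values concentrate care on one provider (COC near 1); large
#'   values disperse it evenly (COC near `1/provider_pool_size`).
#' @param provider_pool_size Number of distinct physicians in each
#'   patient's personal pool.
#' @param p_specialist_predominant Probability that a patient's care is
#'   anchored on a respiratory specialist rather than a family physician.
#' @param outcome_coefficients Named numeric vector of log-odds terms for
#'   the any-admission logistic model. Recognised names: `intercept`,
#'   `low_coci` (the planted continuity effect), `age10` (per decade above
#'   age 60), `male`, `adg` (per comorbidity-score unit above 6), `marg`
#'   (per composite marginalization unit above 3), `rural`. Missing names
#'   default to 0.
#' @param ed_model Named numeric vector for the log-linear count model of ED
#'   visits without admission: `log_rate` (baseline log mean count) and
#'   `low_coci` (log rate ratio for the low-continuity group).
#' @param readmission_model Named numeric vector for the per-episode 30-day
#'   readmission process: `base_logit` (logit probability that an admission
#'   after the first follows within 30 days of the previous discharge) and
#'   `low_coci` (log odds ratio for the low-continuity group).
#' @param admission_count_model Named numeric vector for extra admissions
#'   beyond the first among admitted patients: `log_rate` and `low_coci`
#'   (log rate ratio), feeding a Poisson count.
#' @param censoring_rates Named numeric vector of exponential hazards per
#'   person-year: `death` and `move` (loss of provincial coverage).
#' @param exclusion_rates Named numeric vector of probabilities used to
#'   plant records that exercise the cohort exclusion rules:
#'   `invalid_id`, `non_resident`, `no_coverage`, `prior_copd`.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_copd_claims()], [sim_config_null()]
#' @examples
#' cfg <- sim_config(n_patients = 500, seed = 42)
#' cfg$dispersion_alpha
#' @export
sim_config <- function(n_patients = 1000L,
                       seed = 1L,
                       recruitment_start = "2005-04-01",
                       recruitment_end = "2013-03-31",
                       study_end = "2018-03-31",
                       mean_visits = 37,
                       visit_size = 2.2,
                       dispersion_alpha = 0.159,
                       provider_pool_size = 8L,
                       p_specialist_predominant = 0.057,
                       outcome_coefficients = c(intercept = qlogis(0.35),
                                                low_coci = log(2.25),
                                                age10 = 0.30, male = 0.10,
                                                adg = 0.08, marg = 0.10,
                                                rural = 0.05),
                       ed_model = c(log_rate = log(1.8),
                                    low_coci = log(1.2)),
                       readmission_model = c(base_logit = qlogis(0.25),
                                             low_coci = log(1.4)),
                       admission_count_model = c(log_rate = log(0.8),
                                                 low_coci = log(1.3)),
                       censoring_rates = c(death = 0.030, move = 0.010),
                       exclusion_rates = c(invalid_id = 0.002,
                                           non_resident = 0.002,
                                           no_coverage = 0.003,
                                           prior_copd = 0.005)) {
  check_positive_scalar(n_patients, "n_patients", integer = TRUE)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("configuration error: `seed` must be a single integer.")
  }
  rs <- as_date_scalar(recruitment_start, "recruitment_start")
  re <- as_date_scalar(recruitment_end, "recruitment_end")
  se <- as_date_scalar(study_end, "study_end")
  if (re <= rs) abort("configuration error: `recruitment_end` must be after `recruitment_start`.")
  if (se < re) abort("configuration error: `study_end` must not precede `recruitment_end`.")
  check_positive_scalar(mean_visits, "mean_visits")
  if (mean_visits <= 1) abort("configuration error: `mean_visits` must exceed 1.")
  check_positive_scalar(visit_size, "visit_size")
  check_positive_scalar(dispersion_alpha, "dispersion_alpha")
  check_positive_scalar(provider_pool_size, "provider_pool_size", integer = TRUE)
  check_probability(p_specialist_predominant, "p_specialist_predominant")

  outcome_coefficients <- fill_coefs(outcome_coefficients,
                                     c("intercept", "low_coci", "age10", "male",
                                       "adg", "marg", "rural"),
                                     "outcome_coefficients")
  ed_model <- fill_coefs(ed_model, c("log_rate", "low_coci"), "ed_model")
  readmission_model <- fill_coefs(readmission_model,
                                  c("base_logit", "low_coci"),
                                  "readmission_model")
  admission_count_model <- fill_coefs(admission_count_model,
                                      c("log_rate", "low_coci"),
                                      "admission_count_model")

  censoring_rates <- fill_coefs(censoring_rates, c("death", "move"),
                                "censoring_rates")
  if (any(censoring_rates < 0)) {
    abort("configuration error: `censoring_rates` must be non-negative.")
  }
  exclusion_rates <- fill_coefs(exclusion_rates,
                                c("invalid_id", "non_resident", "no_coverage",
                                  "prior_copd"),
                                "exclusion_rates")
  for (nm in names(exclusion_rates)) {
    check_probability(exclusion_rates[[nm]], paste0("exclusion_rates[", nm, "]"))
  }

  structure(
    list(n_patients = as.integer(n_patients),
         seed = as.integer(seed),
         recruitment_start = rs, recruitment_end = re, study_end = se,
         mean_visits = mean_visits, visit_size = visit_size,
         dispersion_alpha = dispersion_alpha,
         provider_pool_size = as.integer(provider_pool_size),
         p_specialist_predominant = p_specialist_predominant,
         outcome_coefficients = outcome_coefficients,
         ed_model = ed_model,
         readmission_model = readmission_model,
         admission_count_model = admission_count_model,
         censoring_rates = censoring_rates,
         exclusion_rates = exclusion_rates),
    class = "sim_config"
  )
}

fill_coefs <- function(x, expected, what) {
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    abort(sprintf("configuration error: `%s` must be a named numeric vector.", what))
  }
  bad <- setdiff(names(x), expected)
  if (length(bad)) {
    abort(sprintf("configuration error: `%s` has unrecognised name(s): %s.",
                  what, paste(bad, collapse = ", ")))
  }
  if (any(!is.finite(x))) {
    abort(sprintf("configuration error: `%s` must be finite.", what))
  }
  out <- setNames(rep(0, length(expected)), expected)
  out[names(x)] <- x
  out
}

#' Null-effect variant of a simulation configuration
#'
#' Returns the same configuration with every planted low-continuity effect
#' (admission log-odds, ED log rate ratio, readmission log odds ratio, extra
#' admission log rate ratio) set to zero, for calibration studies in which
#' all exposure odds ratios should be 1.
#'
#' @param config A [sim_config()] object (its defaults are used when omitted).
#' @inheritParams sim_config
#' @return A `sim_config` with all `low_coci` terms zeroed.
#' @export
sim_config_null <- function(config = sim_config(), n_patients = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  config$outcome_coefficients[["low_coci"]] <- 0
  config$ed_model[["low_coci"]] <- 0
  config$readmission_model[["low_coci"]] <- 0
  config$admission_count_model[["low_coci"]] <- 0
  if (!is.null(n_patients)) config$n_patients <- as.integer(n_patients)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  config
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d patients, seed %d\n", x$n_patients, x$seed))
  cat(sprintf("  recruitment %s .. %s, study end %s\n",
              format(x$recruitment_start), format(x$recruitment_end),
              format(x$study_end)))
  cat(sprintf("  visits ~ 1 + NB(size %.2f, mean %.1f); Dirichlet alpha %.3f over pool of %d\n",
              x$visit_size, x$mean_visits - 1, x$dispersion_alpha,
              x$provider_pool_size))
  cat(sprintf("  planted low-COCI admission OR %.3f\n",
              exp(x$outcome_coefficients[["low_coci"]])))
  invisible(x)
}
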