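#' Run the full continuity-of-care analysis pipeline
#'
#' Convenience wrapper chaining the whole analysis on a set of linked
#' tables: cohort derivation ([build_cohort()]), continuity profiles
#' ([compute_continuity()]), utilization outcomes
#' ([summarize_utilization()]) and the logistic model suite
#' ([run_model_suite()]).
#'
#' @param tables A named list of linked tables (`persons`, `claims`,
#'   `discharges`, `ed_visits`, optionally `physicians`), e.g. a `coc_sim`
#'   from [simulate_copd_claims()] or the output of
#'   [read_claims_tables()].
#' @inheritParams build_cohort
#' @return A list of class `coc_pipeline` with elements `cohort`,
#'   `profiles`, `outcomes`, `suite`.
#' @examples
#' sim <- simulate_copd_claims(sim_config(n_patients = 600, seed = 21))
#' res <- run_coc_pipeline(sim)
#' res$suite
#' @export
run_coc_pipeline <- function(tables,
                             case_def = copd_case_definition(),
                             recruitment_start = "2005-04-01",
                             recruitment_end = "2013-03-31",
                             min_age = 35,
                             horizon_years = 5,
                             study_end = "2018-03-31") {
  cohort <- build_cohort(tables, case_def, recruitment_start, recruitment_end,
                         min_age, horizon_years, study_end)
  profiles <- compute_continuity(tables$claims, cohort,
                                 persons = tables$persons,
                                 physicians = tables$physicians)
  outcomes <- summarize_utilization(tables$discharges, tables$ed_visits,
                                    cohort, case_def)
  suite <- run_model_suite(profiles, outcomes, tables$persons, cohort)
  structure(list(cohort = cohort, profiles = profiles, outcomes = outcomes,
                 suite = suite),
            class = "coc_pipeline")
}

#' @export
print.coc_pipeline <- function(x, ...) {
  cat("<coc_pipeline>\n")
  cat(sprintf("  cohort: %d screened, %d eligible\n",
              nrow(x$cohort), sum(x$cohort$eligible)))
  cat(sprintf("  profiles: %d, assessed for COCI: %d (median COC %.3f)\n",
              nrow(x$profiles),
              sum(x$profiles$coci_category != "not_assessed"),
              attr(x$profiles, "coci_median")))
  cat("  model suite:\n")
  print(as_tibble(x$suite))
  invisible(x)
}

#' Planted-effect recovery study
#'
#' Generates `n_reps` independent synthetic datasets from `config`, runs
#' the full pipeline on each, and extracts the model-A adjusted odds ratio
#' for the chosen outcome, comparing it against the planted effect.
#' Replicate seeds are derived deterministically from `config$seed`.
#'
#' @param config A [sim_config()]; its `outcome_coefficients["low_coci"]`
#'   is the planted log odds ratio.
#' @param n_reps Number of replicate datasets.
#' @param outcome Outcome whose exposure OR is extracted.
#' @param adjustment_tier Adjustment tier to extract (default `model_A`).
#' @return Tibble with one row per replicate: `rep`, `seed`,
#'   `exposure_or`, `ci_low`, `ci_high`, `n_used`, `covers_truth`.
#'   Attribute `planted_or` holds the planted odds ratio.
#' @examples
#' \donttest{
#' rec <- recover_planted_or(sim_config(n_patients = 2000, seed = 1), n_reps = 3)
#' mean(rec$exposure_or)
#' }
#' @export
recover_planted_or <- function(config, n_reps = 20,
                               outcome = "any_admission",
                               adjustment_tier = "model_A") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  planted <- exp(config$outcome_coefficients[["low_coci"]])

  rows <- purrr::map_dfr(seq_len(n_reps), function(r) {
    cfg <- config
    cfg$seed <- seeds[r]
    sim <- simulate_copd_claims(cfg)
    res <- run_coc_pipeline(sim,
                            recruitment_start = config$recruitment_start,
                            recruitment_end = config$recruitment_end,
                            study_end = config$study_end)
    row <- res$suite %>%
      filter(.data$outcome == .env$outcome,
             .data$adjustment_tier == .env$adjustment_tier)
    tibble(rep = r, seed = seeds[r], exposure_or = row$exposure_or,
           ci_low = row$ci_low, ci_high = row$ci_high, n_used = row$n_used,
           covers_truth = row$ci_low <= planted & planted <= row$ci_high)
  })
  attr(rows, "planted_or") <- planted
  rows
}
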