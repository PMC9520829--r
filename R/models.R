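#' Specify one continuity-utilization logistic model
#'
#' A model spec pairs one binary utilization outcome with an adjustment
#' tier. The exposure is always the dichotomized COCI category with the
#' high-continuity group as reference (configurable for sensitivity
#' checks). Tiers: `unadjusted` (exposure only), `model_A` (age, sex, ADG
#' comorbidity score, socioeconomic status as income quintile plus composite
#' marginalization score, rurality), `model_B` (model A plus predominant
#' provider group).
#'
#' `multiple_readmissions` contrasts patients with 2 or more 30-day
#' readmissions against fewer, fitted with the same logistic machinery as
#' the other outcomes.
#'
#' @param outcome One of `any_admission`, `any_ed_visit`,
#'   `any_readmission_30d`, `multiple_readmissions`.
#' @param adjustment_tier One of `unadjusted`, `model_A`, `model_B`.
#' @param exposure_reference Reference level of the exposure (`"high"` by
#'   default).
#' @return A `model_spec` list with `outcome`, `adjustment_tier`,
#'   `covariates`, `exposure_reference`.
#' @export
model_spec <- function(outcome = c("any_admission", "any_ed_visit",
                                   "any_readmission_30d",
                                   "multiple_readmissions"),
                       adjustment_tier = c("unadjusted", "model_A", "model_B"),
                       exposure_reference = c("high", "low")) {
  outcome <- match.arg(outcome)
  adjustment_tier <- match.arg(adjustment_tier)
  exposure_reference <- match.arg(exposure_reference)
  covariates <- switch(
    adjustment_tier,
    unadjusted = character(),
    model_A = c("age_at_index", "sex", "adg_score", "income_quintile",
                "marg_composite", "rural"),
    model_B = c("age_at_index", "sex", "adg_score", "income_quintile",
                "marg_composite", "rural", "predominant_group")
  )
  structure(list(outcome = outcome, adjustment_tier = adjustment_tier,
                 covariates = covariates,
                 exposure_reference = exposure_reference),
            class = "model_spec")
}

#' Assemble the model-ready design table
#'
#' Joins continuity profiles, utilization outcomes, the person registry and
#' the cohort (for age at index) into one row per patient assessed for
#' continuity (patients with `not_assessed` COCI category are dropped),
#' with the binary outcome, the exposure factor, and the spec's covariates.
#'
#' @param profiles Continuity profiles from [compute_continuity()].
#' @param outcomes Utilization summary from [summarize_utilization()].
#' @param persons Person registry (covariate source).
#' @param cohort Cohort tibble (supplies `age_at_index`).
#' @param spec A [model_spec()].
#' @return Tibble with columns `patient_id`, `outcome` (0/1), `exposure`
#'   (factor, reference first), and the spec's covariates.
#' @export
build_design <- function(profiles, outcomes, persons, cohort,
                         spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  df <- profiles %>%
    filter(.data$coci_category %in% c("low", "high")) %>%
    inner_join(outcomes, by = "patient_id") %>%
    inner_join(cohort %>% select("patient_id", "age_at_index"),
               by = "patient_id") %>%
    left_join(persons %>%
                select(dplyr::any_of(c("patient_id", "sex", "adg_score",
                                       "income_quintile", "marg_composite",
                                       "rural"))),
              by = "patient_id")

  y <- switch(spec$outcome,
              any_admission = df$any_admission,
              any_ed_visit = df$any_ed_visit,
              any_readmission_30d = df$any_readmission_30d,
              multiple_readmissions = df$n_readmissions_30d >= 2L)
  ref <- spec$exposure_reference
  other <- setdiff(c("high", "low"), ref)
  design <- tibble(
    patient_id = df$patient_id,
    outcome = as.integer(y),
    exposure = factor(as.character(df$coci_category), levels = c(ref, other))
  )
  for (v in spec$covariates) {
    col <- df[[v]]
    if (is.null(col)) abort(sprintf("covariate `%s` not found in inputs.", v))
    if (v %in% c("sex", "income_quintile", "predominant_group")) {
      col <- factor(col)
    }
    if (v == "rural") col <- as.logical(col)
    design[[v]] <- col
  }
  for (v in c("exposure", spec$covariates)) {
    if (length(unique(design[[v]])) < 2L) {
      abort(sprintf("covariate `%s` has a single level in the design.", v))
    }
  }
  attr(design, "spec") <- spec
  design
}

#' Fit one continuity-utilization logistic model
#'
#' Maximum-likelihood logistic regression of the binary outcome on the
#' low-continuity exposure and the spec's covariates, with a Wald 95%
#' confidence interval on the exposure odds ratio,
#' \eqn{\exp(\beta \pm 1.96\,SE)}. Perfect separation or other failures to
#' converge are reported via `converged = FALSE` rather than an error.
#'
#' @param design Output of [build_design()].
#' @return A `coc_fit` object: list with `spec`, `coefficients`, `se`,
#'   `exposure_term`, `exposure_or`, `ci95`, `n_used`, `converged`.
#' @export
fit_continuity_model <- function(design) {
  spec <- attr(design, "spec") %||% model_spec()
  if (length(unique(design$outcome)) < 2L) {
    abort("outcome must have both levels present.")
  }
  rhs <- paste(c("exposure", spec$covariates), collapse = " + ")
  fml <- stats::as.formula(paste("outcome ~", rhs))

  separation <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = design, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  other <- setdiff(c("high", "low"), spec$exposure_reference)
  term <- paste0("exposure", other)
  beta <- cf[[term]]
  # complete separation can pass glm's own convergence check with an
  # exploding coefficient and standard error; treat that as non-convergence
  degenerate <- !is.finite(beta) || !is.finite(se[[term]]) ||
    abs(beta) > 15 || se[[term]] > 50
  converged <- isTRUE(fit$converged) && !separation && all(is.finite(se)) &&
    !degenerate

  structure(
    list(spec = spec,
         coefficients = cf,
         se = se,
         exposure_term = term,
         exposure_or = exp(beta),
         ci95 = exp(beta + c(-1, 1) * 1.96 * se[[term]]),
         n_used = stats::nobs(fit),
         converged = converged),
    class = "coc_fit"
  )
}

#' @export
print.coc_fit <- function(x, ...) {
  cat(sprintf("<coc_fit> %s ~ low COCI (%s), n = %d\n",
              x$spec$outcome, x$spec$adjustment_tier, x$n_used))
  cat(sprintf("  exposure OR %.3f (95%% CI %.3f, %.3f)%s\n",
              x$exposure_or, x$ci95[1], x$ci95[2],
              if (x$converged) "" else " [did not converge]"))
  invisible(x)
}

#' @export
tidy.coc_fit <- function(x, exponentiate = FALSE, ...) {
  est <- x$coefficients
  se <- x$se
  out <- tibble(term = names(est), estimate = unname(est),
                std.error = unname(se),
                statistic = unname(est / se),
                p.value = 2 * stats::pnorm(abs(unname(est / se)),
                                           lower.tail = FALSE),
                conf.low = unname(est - 1.96 * se),
                conf.high = unname(est + 1.96 * se))
  if (exponentiate) {
    out <- out %>% mutate(across(c("estimate", "conf.low", "conf.high"), exp))
  }
  out
}

#' @export
glance.coc_fit <- function(x, ...) {
  tibble(outcome = x$spec$outcome, adjustment_tier = x$spec$adjustment_tier,
         exposure_or = x$exposure_or, ci_low = x$ci95[1], ci_high = x$ci95[2],
         n_used = x$n_used, converged = x$converged)
}

#' Fit the full continuity-utilization model suite
#'
#' Fits the 4 outcomes (any admission, any ED visit, any 30-day
#' readmission, multiple readmissions) by 3 adjustment tiers (unadjusted,
#' model A, model B) — 12 logistic models — and returns one row per model
#' with the low-COCI exposure odds ratio and Wald 95% CI.
#'
#' @inheritParams build_design
#' @return A tibble of class `coc_suite`: columns `outcome`,
#'   `adjustment_tier`, `exposure_or`, `ci_low`, `ci_high`, `n_used`,
#'   `converged`, in fixed outcome-by-tier order. The underlying `coc_fit`
#'   objects are kept in the `fits` attribute.
#' @examples
#' sim <- simulate_copd_claims(sim_config(n_patients = 800, seed = 9))
#' cohort <- build_cohort(sim)
#' profiles <- compute_continuity(sim$claims, cohort)
#' outcomes <- summarize_utilization(sim$discharges, sim$ed_visits, cohort)
#' suite <- run_model_suite(profiles, outcomes, sim$persons, cohort)
#' suite
#' @export
run_model_suite <- function(profiles, outcomes, persons, cohort) {
  outs <- c("any_admission", "any_ed_visit", "any_readmission_30d",
            "multiple_readmissions")
  tiers <- c("unadjusted", "model_A", "model_B")
  grid <- expand.grid(outcome = outs, adjustment_tier = tiers,
                      stringsAsFactors = FALSE) %>%
    arrange(match(.data$outcome, outs), match(.data$adjustment_tier, tiers))

  fits <- purrr::pmap(grid, function(outcome, adjustment_tier) {
    sp <- model_spec(outcome, adjustment_tier)
    tryCatch(
      fit_continuity_model(build_design(profiles, outcomes, persons, cohort, sp)),
      error = function(e) {
        abort(sprintf("model %s / %s failed: %s", outcome, adjustment_tier,
                      conditionMessage(e)))
      }
    )
  })
  out <- purrr::map_dfr(fits, glance)
  attr(out, "fits") <- fits
  class(out) <- c("coc_suite", class(out))
  out
}

#' Forest plot of the model-suite odds ratios
#'
#' @param object A `coc_suite` from [run_model_suite()].
#' @param ... Unused.
#' @return A ggplot object: exposure OR with 95% CI per outcome, faceted by
#'   adjustment tier, on a log scale with the null at 1.
#' @export
autoplot.coc_suite <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$exposure_or, y = .data$outcome)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~adjustment_tier) +
    ggplot2::labs(x = "Low-COCI odds ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Negative-binomial readmission-count model
#'
#' Companion count model for the number of 30-day readmissions: a
#' negative-binomial regression of the readmission count on the
#' low-continuity exposure and the model-A covariates. This is an
#' alternative characterization of the readmission burden; the primary
#' suite dichotomizes the count and uses logistic regression throughout.
#' Requires the MASS package.
#'
#' @inheritParams build_design
#' @return A tibble with the exposure rate ratio and Wald 95% CI.
#' @export
fit_readmission_count_model <- function(profiles, outcomes, persons, cohort) {
  if (!requireNamespace("MASS", quietly = TRUE)) {
    abort("fit_readmission_count_model() requires the MASS package.")
  }
  sp <- model_spec("any_readmission_30d", "model_A")
  design <- build_design(profiles, outcomes, persons, cohort, sp)
  design$count <- outcomes$n_readmissions_30d[
    match(design$patient_id, outcomes$patient_id)]
  rhs <- paste(c("exposure", sp$covariates), collapse = " + ")
  fit <- MASS::glm.nb(stats::as.formula(paste("count ~", rhs)), data = design)
  beta <- coef(fit)[["exposurelow"]]
  se <- sqrt(diag(vcov(fit)))[["exposurelow"]]
  tibble(term = "low COCI", rate_ratio = exp(beta),
         ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
         n_used = stats::nobs(fit), theta = fit$theta)
}
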