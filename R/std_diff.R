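#' Standardized differences between two groups
#'
#' Scale-free contrasts used in place of p-values in cohort description
#' tables; values below 0.1 conventionally indicate negligible imbalance.
#'
#' * `std_diff_continuous()`:
#'   \eqn{d = |m_1 - m_2| / \sqrt{(s_1^2 + s_2^2)/2}}.
#' * `std_diff_binary()`:
#'   \eqn{d = |p_1 - p_2| / \sqrt{(p_1(1-p_1) + p_2(1-p_2))/2}}.
#' * `std_diff_categorical()`: Mahalanobis-type distance
#'   \eqn{d = \sqrt{T' S^{-1} T}} over the first \eqn{L-1} category
#'   proportions, where \eqn{T} is the vector of proportion differences and
#'   \eqn{S} the average of the two multinomial covariance matrices
#'   (Yang-Dalton construction). Reduces exactly to the binary form at
#'   \eqn{L = 2}.
#'
#' When both variances are zero the difference is degenerate: identical
#' groups return 0, differing groups return `Inf` with a warning.
#'
#' @param mean1,sd1,mean2,sd2 Group means and standard deviations.
#' @param p1,p2 Group proportions in \[0, 1\].
#' @param props1,props2 Category proportion vectors of equal length (each
#'   summing to 1 within 1e-9).
#' @return A non-negative standardized difference.
#' @examples
#' std_diff_continuous(1.42, 2.27, 0.72, 1.32) # ~0.38
#' std_diff_binary(0.5, 0.3)                   # ~0.417
#' std_diff_categorical(c(0.6, 0.4), c(0.4, 0.6))
#' @name std_diff
NULL

#' @rdname std_diff
#' @export
std_diff_continuous <- function(mean1, sd1, mean2, sd2) {
  if (any(c(sd1, sd2) < 0)) abort("standard deviations must be non-negative.")
  pooled <- sqrt((sd1^2 + sd2^2) / 2)
  if (pooled == 0) {
    if (mean1 == mean2) return(0)
    warn("Both groups have zero variance but different means; standardized difference is infinite.")
    return(Inf)
  }
  abs(mean1 - mean2) / pooled
}

#' @rdname std_diff
#' @export
std_diff_binary <- function(p1, p2) {
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1)) {
    abort("proportions must lie in [0, 1].")
  }
  v <- (p1 * (1 - p1) + p2 * (1 - p2)) / 2
  if (v == 0) {
    if (p1 == p2) return(0)
    warn("Both groups have degenerate proportions; standardized difference is infinite.")
    return(Inf)
  }
  abs(p1 - p2) / sqrt(v)
}

#' @rdname std_diff
#' @export
std_diff_categorical <- function(props1, props2) {
  L <- length(props1)
  if (length(props2) != L) abort("`props1` and `props2` must have the same length.")
  if (L < 2) abort("categorical standardized difference needs at least 2 categories.")
  if (abs(sum(props1) - 1) > 1e-9 || abs(sum(props2) - 1) > 1e-9) {
    abort("each proportion vector must sum to 1.")
  }
  if (identical(as.numeric(props1), as.numeric(props2))) return(0)
  # categories empty in both groups carry no information and would make the
  # multinomial covariance singular
  keep <- props1 + props2 > 0
  props1 <- props1[keep]; props2 <- props2[keep]
  L <- length(props1)
  if (L < 2) return(0)
  p1 <- props1[-L]; p2 <- props2[-L]
  T_ <- p1 - p2
  S <- (diag(p1, nrow = L - 1) - outer(p1, p1) +
          diag(p2, nrow = L - 1) - outer(p2, p2)) / 2
  sol <- tryCatch(solve(S, T_), error = function(e) {
    warn("Singular covariance in categorical standardized difference; returning Inf.")
    NULL
  })
  if (is.null(sol)) return(Inf)
  sqrt(drop(T_ %*% sol))
}

#' Descriptive comparison table between two patient groups
#'
#' Builds the descriptive utilization/characteristics table contrasting two
#' groups of patients (low vs high COCI category, or FP vs SP predominant
#' provider group): per variable, binned counts with percentages and a
#' standardized difference (categorical over the count bins, continuous for
#' means, binary for flags).
#'
#' @param profiles Continuity profiles from [compute_continuity()].
#' @param outcomes Utilization summaries from [summarize_utilization()].
#' @param persons Optional person registry (adds demographic rows when
#'   supplied).
#' @param grouping `"coci_category"` (low vs high; `not_assessed` patients
#'   are dropped) or `"predominant_group"` (FP vs SP).
#' @return A tibble of class `coc_comparison`: one row per variable level
#'   with columns `variable`, `level`, `stat`, per-group `n`/`pct` (or
#'   mean/sd), and `std_diff` on the variable's first row.
#' @examples
#' sim <- simulate_copd_claims(sim_config(n_patients = 400, seed = 2))
#' cohort <- build_cohort(sim)
#' profiles <- compute_continuity(sim$claims, cohort, sim$persons, sim$physicians)
#' outcomes <- summarize_utilization(sim$discharges, sim$ed_visits, cohort)
#' build_comparison_table(profiles, outcomes, grouping = "coci_category")
#' @export
build_comparison_table <- function(profiles, outcomes, persons = NULL,
                                   grouping = c("coci_category",
                                                "predominant_group")) {
  grouping <- match.arg(grouping)
  df <- profiles %>% inner_join(outcomes, by = "patient_id")
  if (grouping == "coci_category") {
    df <- df %>% filter(.data$coci_category %in% c("low", "high"))
    df$group <- factor(df$coci_category, levels = c("low", "high"))
  } else {
    df$group <- factor(df$predominant_group, levels = c("FP", "SP"))
  }
  if (!is.null(persons)) {
    df <- df %>% left_join(persons, by = "patient_id")
  }
  tab <- table(df$group)
  if (any(tab == 0)) {
    abort(sprintf("Empty comparison group: %s.",
                  paste(names(tab)[tab == 0], collapse = ", ")))
  }
  g1 <- levels(df$group)[1]; g2 <- levels(df$group)[2]

  rows <- list()
  binned_vars <- c("n_admissions_all", "n_admissions_copd", "n_ed_all",
                   "n_ed_copd", "n_ed_with_admission")
  labels <- c(n_admissions_all = "Hospital admissions (any cause)",
              n_admissions_copd = "Hospital admissions (COPD related)",
              n_ed_all = "ED visits (any cause)",
              n_ed_copd = "ED visits (COPD related)",
              n_ed_with_admission = "ED visits with hospital admission")
  for (v in binned_vars) {
    rows[[v]] <- binned_comparison(df, v, labels[[v]], g1, g2)
    rows[[paste0(v, "_mean")]] <- continuous_comparison(
      df, v, paste("Mean", tolower(labels[[v]])), g1, g2)
  }
  for (v in c("any_readmission_30d", "died_in_hospital")) {
    lab <- c(any_readmission_30d = "30 day readmission",
             died_in_hospital = "Discharge due to death")[[v]]
    rows[[v]] <- binary_comparison(df, v, lab, g1, g2)
  }
  if (!is.null(persons) && "adg_score" %in% names(df)) {
    rows[["adg"]] <- continuous_comparison(df, "adg_score", "ADG comorbidity score",
                                           g1, g2)
    if ("rural" %in% names(df)) {
      rows[["rural"]] <- binary_comparison(df, "rural", "Rural residence", g1, g2)
    }
  }
  out <- bind_rows(rows)
  attr(out, "group_sizes") <- setNames(as.integer(tab), names(tab))
  attr(out, "grouping") <- grouping
  class(out) <- c("coc_comparison", class(out))
  out
}

binned_comparison <- function(df, var, label, g1, g2) {
  df$bin <- bin_utilization_count(df[[var]])
  counts <- df %>% count(.data$group, .data$bin, .drop = FALSE)
  c1 <- counts %>% filter(.data$group == g1)
  c2 <- counts %>% filter(.data$group == g2)
  p1 <- c1$n / sum(c1$n); p2 <- c2$n / sum(c2$n)
  tibble(variable = label, level = as.character(c1$bin), stat = "n (%)",
         n_1 = c1$n, pct_1 = round(100 * p1, 1),
         n_2 = c2$n, pct_2 = round(100 * p2, 1),
         std_diff = c(std_diff_categorical(p1, p2),
                      rep(NA_real_, length(p1) - 1)))
}

continuous_comparison <- function(df, var, label, g1, g2) {
  x <- df[[var]]
  m1 <- mean(x[df$group == g1]); s1 <- sd(x[df$group == g1])
  m2 <- mean(x[df$group == g2]); s2 <- sd(x[df$group == g2])
  tibble(variable = label, level = "", stat = "mean ± SD",
         n_1 = NA_integer_, pct_1 = NA_real_, n_2 = NA_integer_, pct_2 = NA_real_,
         mean_1 = m1, sd_1 = s1, mean_2 = m2, sd_2 = s2,
         std_diff = std_diff_continuous(m1, s1, m2, s2))
}

binary_comparison <- function(df, var, label, g1, g2) {
  x <- as.logical(df[[var]])
  p1 <- mean(x[df$group == g1]); p2 <- mean(x[df$group == g2])
  tibble(variable = label, level = "yes", stat = "n (%)",
         n_1 = sum(x[df$group == g1]), pct_1 = round(100 * p1, 1),
         n_2 = sum(x[df$group == g2]), pct_2 = round(100 * p2, 1),
         std_diff = std_diff_binary(p1, p2))
}

#' @export
print.coc_comparison <- function(x, ...) {
  gs <- attr(x, "group_sizes")
  cat(sprintf("<coc_comparison> grouped by %s (%s n=%d vs %s n=%d)\n",
              attr(x, "grouping"), names(gs)[1], gs[1], names(gs)[2], gs[2]))
  NextMethod()
}

#' Plot the standardized differences of a comparison table
#'
#' Dot plot of the standardized difference per variable, with the
#' conventional 0.1 negligible-imbalance threshold marked.
#'
#' @param object A `coc_comparison` from [build_comparison_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coc_comparison <- function(object, ...) {
  dat <- object %>%
    filter(!is.na(.data$std_diff), is.finite(.data$std_diff)) %>%
    distinct(.data$variable, .data$stat, .keep_all = TRUE)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$std_diff,
                                    y = stats::reorder(.data$variable, .data$std_diff))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = 0.1, linetype = "dashed") +
    ggplot2::labs(x = "Standardized difference", y = NULL,
                  title = paste("Group imbalance by", attr(object, "grouping"))) +
    ggplot2::theme_minimal()
}
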