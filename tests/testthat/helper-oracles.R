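# Independent brute-force oracles used to check the analytic index formulas.

# probability that two distinct visits (drawn without replacement) share a
# provider, by exhaustive pair enumeration
oracle_pair_concordance <- function(providers) {
  N <- length(providers)
  pairs <- utils::combn(N, 2)
  mean(providers[pairs[1, ]] == providers[pairs[2, ]])
}

# generalized (Mahalanobis-type) standardized difference for a multinomial,
# built element-by-element with explicit loops
oracle_std_diff_categorical <- function(p1, p2) {
  L <- length(p1)
  keep <- (p1 + p2) > 0
  p1 <- p1[keep]; p2 <- p2[keep]
  L <- length(p1)
  T_ <- numeric(L - 1)
  S <- matrix(0, L - 1, L - 1)
  for (k in seq_len(L - 1)) {
    T_[k] <- p1[k] - p2[k]
    for (l in seq_len(L - 1)) {
      if (k == l) {
        S[k, l] <- (p1[k] * (1 - p1[k]) + p2[k] * (1 - p2[k])) / 2
      } else {
        S[k, l] <- -(p1[k] * p1[l] + p2[k] * p2[l]) / 2
      }
    }
  }
  sqrt(drop(t(T_) %*% solve(S) %*% T_))
}

random_provider_sequence <- function(max_n = 8, max_k = 4) {
  N <- sample(2:max_n, 1)
  sample(LETTERS[seq_len(sample(2:max_k, 1))], N, replace = TRUE)
}

# minimal one-patient cohort row with a fixed follow-up window
tiny_cohort <- function(patient_id = "P1", index = "2010-01-01",
                        end = "2015-01-01") {
  tibble::tibble(patient_id = patient_id,
                 index_date = as.Date(index),
                 age_at_index = 60,
                 eligible = TRUE,
                 exclusion_reason = NA_character_,
                 followup_start = as.Date(index),
                 followup_end = as.Date(end),
                 censor_reason = "end_of_window")
}

tiny_claims <- function(patient_id, dates, physicians,
                        specialty = "FP", code = "Z00") {
  tibble::tibble(patient_id = patient_id,
                 physician_id = physicians,
                 specialty = specialty,
                 service_date = as.Date(dates),
                 diagnosis_code = code,
                 setting = "outpatient")
}
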