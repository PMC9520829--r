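persons_one <- function(id = "P1", birth = "1950-06-01", ...) {
  tibble::tibble(patient_id = id, birth_date = as.Date(birth),
                 death_date = as.Date(NA),
                 resident_of_province = TRUE,
                 coverage_start = as.Date(birth),
                 coverage_end = as.Date("2030-01-01"), ...)
}

test_that("index date is the earliest qualifying in-window event", {
  claims <- tiny_claims("P1", "2006-03-10", "FP01", code = "492")
  idx <- find_index_dates(claims)
  expect_identical(idx$index_date, as.Date("2006-03-10"))
  expect_false(idx$prior_copd)
  expect_identical(idx$index_source, "claim")

  # later in-window event does not displace an earlier one
  claims2 <- tiny_claims("P1", c("2007-01-01", "2006-03-10"), c("FP01", "FP02"),
                         code = c("J44", "491"))
  expect_identical(find_index_dates(claims2)$index_date, as.Date("2006-03-10"))
})

test_that("pre-window COPD history yields prior_copd with no index date", {
  claims <- tiny_claims("P1", c("2004-11-01", "2007-01-01"), c("FP01", "FP01"),
                        code = c("J44", "496"))
  idx <- find_index_dates(claims)
  expect_true(idx$prior_copd)
  expect_true(is.na(idx$index_date))
})

test_that("non-COPD codes never qualify and code matching is prefix-based", {
  claims <- tiny_claims("P1", "2006-01-01", "FP01", code = "J18")
  expect_identical(nrow(find_index_dates(claims)), 0L)
  claims_sub <- tiny_claims("P1", "2006-01-01", "FP01", code = "J44.1")
  expect_identical(find_index_dates(claims_sub)$index_date, as.Date("2006-01-01"))
})

test_that("discharges qualify on the most-responsible code, dated by admission", {
  claims <- tiny_claims("P1", "2010-05-05", "FP01", code = "Z00")
  disch <- tibble::tibble(patient_id = "P1", admit_date = as.Date("2008-02-02"),
                          discharge_date = as.Date("2008-02-08"),
                          mrd_code = "J43")
  idx <- find_index_dates(claims, disch)
  expect_identical(idx$index_date, as.Date("2008-02-02"))
  expect_identical(idx$index_source, "discharge")
})

test_that("malformed diagnosis codes are skipped, warned about and counted", {
  claims <- tiny_claims("P1", c("2006-01-01", "2007-01-01"), c("FP01", "FP01"),
                        code = c("", "492"))
  expect_warning(idx <- find_index_dates(claims), "malformed")
  expect_identical(attr(idx, "rejected_codes"), 1L)
  expect_identical(idx$index_date, as.Date("2007-01-01"))
})

test_that("exclusions apply with fixed precedence and exactly one reason", {
  persons <- dplyr::bind_rows(
    persons_one("P1"),
    persons_one("X-1!"),                                  # invalid id
    persons_one("P3") |> dplyr::mutate(resident_of_province = FALSE),
    persons_one("P4") |> dplyr::mutate(coverage_end = as.Date("2005-12-31")),
    persons_one("P5", birth = "1971-06-01")               # 34.9y at index
  )
  idx <- tibble::tibble(
    patient_id = c("P1", "X-1!", "P3", "P4", "P5"),
    index_date = as.Date("2006-04-01"),
    index_source = "claim",
    prior_copd = FALSE
  )
  cohort <- apply_exclusions(persons, idx)
  expect_identical(cohort$exclusion_reason,
                   c(NA, "invalid_id", "non_resident", "no_coverage", "under_35"))
  expect_identical(cohort$eligible, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_lt(cohort$age_at_index[5], 35)

  # an invalid id beats any later-listed reason
  both <- apply_exclusions(persons_one("X-1!"),
                           idx[idx$patient_id == "X-1!", ] |>
                             dplyr::mutate(prior_copd = TRUE))
  expect_identical(both$exclusion_reason, "invalid_id")
})

test_that("no triggered exclusions conserves every indexed patient as eligible", {
  persons <- dplyr::bind_rows(lapply(sprintf("P%d", 1:7), persons_one))
  idx <- tibble::tibble(patient_id = persons$patient_id,
                        index_date = as.Date("2006-04-01"),
                        index_source = "claim", prior_copd = FALSE)
  cohort <- apply_exclusions(persons, idx)
  expect_identical(sum(cohort$eligible), 7L)
})

test_that("follow-up is censored at the earliest of four dates, with reasons", {
  base <- tibble::tibble(patient_id = "P1", index_date = as.Date("2010-01-01"),
                         age_at_index = 60, eligible = TRUE,
                         exclusion_reason = NA_character_)

  fu <- define_followup(base, persons_one("P1"))
  expect_identical(fu$followup_end, as.Date("2015-01-01"))
  expect_identical(fu$censor_reason, "end_of_window")

  died <- persons_one("P1") |> dplyr::mutate(death_date = as.Date("2012-01-01"))
  fu2 <- define_followup(base, died)
  expect_identical(fu2$followup_end, as.Date("2012-01-01"))
  expect_identical(fu2$censor_reason, "death")

  # min-date oracle over the three candidate censoring dates
  moved <- persons_one("P1") |>
    dplyr::mutate(coverage_end = as.Date("2013-01-01"),
                  death_date = as.Date("2014-01-01"))
  expected_end <- min(as.Date("2015-01-01"), as.Date("2014-01-01"),
                      as.Date("2013-01-01"), as.Date("2018-03-31"))
  fu3 <- define_followup(base, moved)
  expect_identical(fu3$followup_end, expected_end)
  expect_identical(fu3$censor_reason, "moved")

  late <- base |> dplyr::mutate(index_date = as.Date("2016-01-01"))
  fu4 <- define_followup(late, persons_one("P1"))
  expect_identical(fu4$followup_end, as.Date("2018-03-31"))
  expect_identical(fu4$censor_reason, "end_of_window")
})

test_that("death before index is a data-integrity error", {
  base <- tibble::tibble(patient_id = "P1", index_date = as.Date("2010-01-01"),
                         age_at_index = 60, eligible = TRUE,
                         exclusion_reason = NA_character_)
  dead <- persons_one("P1") |> dplyr::mutate(death_date = as.Date("2009-06-01"))
  expect_error(define_followup(base, dead), "data-integrity")
})

test_that("cohort building is deterministic and partitions qualifying patients", {
  sim <- simulate_copd_claims(sim_config(n_patients = 300, seed = 61))
  c1 <- build_cohort(sim)
  c2 <- build_cohort(sim)
  expect_identical(c1, c2)
  expect_true(all(xor(c1$eligible, !is.na(c1$exclusion_reason))))
  expect_true(all(c1$eligible | c1$exclusion_reason %in%
                    c("invalid_id", "non_resident", "no_coverage",
                      "prior_copd", "under_35")))
  # follow-up never exceeds the 5-year horizon
  span <- as.numeric(c1$followup_end - c1$followup_start)[c1$eligible]
  expect_true(all(span <= 5 * 366))
  expect_true(all(span >= 0))
})

test_that("shrinking the recruitment window never adds cohort members", {
  sim <- simulate_copd_claims(sim_config(n_patients = 300, seed = 62))
  wide <- build_cohort(sim)
  narrow <- build_cohort(sim, recruitment_start = "2007-04-01",
                         recruitment_end = "2011-03-31")
  wide_elig <- wide$patient_id[wide$eligible]
  narrow_elig <- narrow$patient_id[narrow$eligible]
  expect_true(all(narrow_elig %in% wide_elig))
  expect_lte(length(narrow_elig), length(wide_elig))
})
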