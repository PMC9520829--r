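mk_discharges <- function(patient_id, admit, discharge,
                          mrd = "I10", category = "emergent", died = FALSE) {
  tibble::tibble(patient_id = patient_id,
                 admit_date = as.Date(admit),
                 discharge_date = as.Date(discharge),
                 mrd_code = mrd,
                 admission_category = category,
                 died_in_hospital = died)
}

test_that("admissions are counted inside the half-open follow-up window", {
  cohort <- tiny_cohort()
  disch <- mk_discharges("P1",
                         c("2010-06-01", "2012-03-01", "2015-01-01"),
                         c("2010-06-05", "2012-03-04", "2015-01-03"),
                         mrd = c("J44", "I10", "J44"))
  out <- count_admissions(disch, cohort)
  # the admission on the follow-up end date is outside [start, end)
  expect_identical(out$n_admissions_all, 2L)
  expect_identical(out$n_admissions_copd, 1L)
  expect_true(out$any_admission)
})

test_that("admission counts match an independent filter-and-count oracle", {
  sim <- simulate_copd_claims(sim_config(n_patients = 250, seed = 33))
  cohort <- build_cohort(sim)
  out <- count_admissions(sim$discharges, cohort)
  elig <- cohort[cohort$eligible, ]
  oracle <- vapply(seq_len(nrow(elig)), function(i) {
    d <- sim$discharges[sim$discharges$patient_id == elig$patient_id[i], ]
    sum(d$admit_date >= elig$followup_start[i] &
          d$admit_date < elig$followup_end[i])
  }, numeric(1))
  expect_equal(out$n_admissions_all[match(elig$patient_id, out$patient_id)],
               as.integer(oracle))
})

test_that("30-day readmission window is (0, 30] and excludes elective/transfer", {
  cohort <- tiny_cohort()
  day30 <- mk_discharges("P1", c("2010-01-01", "2010-02-05"),
                         c("2010-01-06", "2010-02-09"))
  day30$admit_date[2] <- as.Date("2010-01-06") + 30
  expect_identical(flag_30day_readmissions(day30, cohort)$n_readmissions_30d, 1L)

  day31 <- day30
  day31$admit_date[2] <- as.Date("2010-01-06") + 31
  expect_identical(flag_30day_readmissions(day31, cohort)$n_readmissions_30d, 0L)

  transfer <- mk_discharges("P1", c("2010-01-01", "2010-01-10"),
                            c("2010-01-06", "2010-01-12"),
                            category = c("emergent", "transfer"))
  expect_identical(flag_30day_readmissions(transfer, cohort)$n_readmissions_30d, 0L)

  elective <- transfer
  elective$admission_category[2] <- "elective"
  expect_identical(flag_30day_readmissions(elective, cohort)$n_readmissions_30d, 0L)
})

test_that("overlapping stays merge into one episode before readmission logic", {
  cohort <- tiny_cohort()
  nested <- mk_discharges("P1", c("2010-01-01", "2010-01-03"),
                          c("2010-01-10", "2010-01-05"))
  expect_warning(out <- flag_30day_readmissions(nested, cohort), "Merged")
  expect_identical(out$n_readmissions_30d, 0L)
  expect_warning(adm <- count_admissions(nested, cohort), "Merged")
  expect_identical(adm$n_admissions_all, 1L)
})

test_that("no readmissions are possible with at most one admission", {
  sim <- simulate_copd_claims(sim_config(n_patients = 300, seed = 44))
  cohort <- build_cohort(sim)
  out <- summarize_utilization(sim$discharges, sim$ed_visits, cohort)
  expect_true(all(out$n_readmissions_30d[out$n_admissions_all <= 1] == 0))
  expect_true(all(out$n_ed_with_admission + out$n_ed_without_admission ==
                    out$n_ed_all))
  expect_true(all(out$n_admissions_copd <= out$n_admissions_all))
  expect_identical(out$any_admission, out$n_admissions_all >= 1L)
})

test_that("ED visits classify by admission linkage and scheduled status", {
  cohort <- tiny_cohort()
  ed <- tibble::tibble(
    patient_id = "P1",
    visit_date = as.Date(c("2010-02-01", "2010-03-01", "2010-04-01", "2010-05-01")),
    diagnosis_code = c("J44", "I10", "Z00", "491"),
    admitted = c(TRUE, FALSE, FALSE, FALSE),
    scheduled = FALSE
  )
  disch <- mk_discharges("P1", "2010-02-01", "2010-02-05")
  out <- classify_ed_visits(ed, disch, cohort)
  expect_identical(out$n_ed_all, 4L)
  expect_identical(out$n_ed_with_admission, 1L)
  expect_identical(out$n_ed_without_admission, 3L)
  expect_identical(out$n_ed_copd, 2L)

  sched <- ed
  sched$scheduled[1] <- TRUE
  out2 <- classify_ed_visits(sched, disch, cohort)
  expect_identical(out2$n_ed_with_admission, 0L)
  expect_identical(out2$n_ed_without_admission, 4L)

  # admitted flag with no matching discharge is a linkage defect
  expect_warning(out3 <- classify_ed_visits(ed, mk_discharges("P1", "2011-01-01",
                                                              "2011-01-05"),
                                            cohort),
                 "no matching discharge")
  expect_identical(out3$n_ed_with_admission, 0L)
  expect_identical(attr(out3, "linkage_defects"), 1L)
})

test_that("in-hospital death is discharge-based and windowed", {
  cohort <- tiny_cohort()
  death_ep <- mk_discharges("P1", "2011-01-01", "2011-01-09", died = TRUE)
  expect_true(in_hospital_death(death_ep, cohort)$died_in_hospital)
  no_ep <- mk_discharges("P1", "2011-01-01", "2011-01-09", died = FALSE)
  expect_false(in_hospital_death(no_ep, cohort)$died_in_hospital)
  late_ep <- mk_discharges("P1", "2016-01-01", "2016-01-09", died = TRUE)
  expect_false(in_hospital_death(late_ep, cohort)$died_in_hospital)
})

test_that("count bins match the reporting categories", {
  expect_identical(as.character(bin_utilization_count(c(0, 1, 5, 6, 10, 11, 40))),
                   c("0", "1 to 5", "1 to 5", "6 to 10", "6 to 10", "> 10", "> 10"))
  expect_error(bin_utilization_count(-1), "non-negative")
})

test_that("outcomes are invariant to input row order", {
  sim <- simulate_copd_claims(sim_config(n_patients = 150, seed = 55))
  cohort <- build_cohort(sim)
  out1 <- summarize_utilization(sim$discharges, sim$ed_visits, cohort)
  set.seed(1)
  disch_shuf <- sim$discharges[sample(nrow(sim$discharges)), ]
  ed_shuf <- sim$ed_visits[sample(nrow(sim$ed_visits)), ]
  out2 <- summarize_utilization(disch_shuf, ed_shuf, cohort)
  out2 <- out2[match(out1$patient_id, out2$patient_id), ]
  expect_equal(as.data.frame(out1), as.data.frame(out2), ignore_attr = TRUE)
})
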