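test_that("UPC matches hand counts and boundary cases", {
  expect_equal(upc_index(rep("A", 9)), 1)
  expect_equal(upc_index(c("A", "A", "B")), 2 / 3)
  expect_equal(upc_index(c(1, 1, 1, 1)), 0.25)   # uniform counts: 1/k
  expect_equal(upc_index(c(2, 1)), 2 / 3)        # counts form
  expect_error(upc_index(character()), "N = 0")
})

test_that("COC matches its definition at the extremes and by hand", {
  expect_equal(coc_index(LETTERS[1:6]), 0)       # every visit a new provider
  expect_equal(coc_index(rep("A", 6)), 1)        # a single provider
  expect_equal(coc_index(c(2, 2)), 1 / 3)
  expect_equal(coc_index(c(2, 2)), oracle_pair_concordance(c("A", "A", "B", "B")))
  expect_error(coc_index("A"), "fewer than 2")
})

test_that("SECON reflects visit order", {
  expect_equal(secon_index(c("A", "B", "A", "B")), 0)
  expect_equal(secon_index(c("A", "A", "A")), 1)
  expect_equal(secon_index(c("A", "A", "B", "B")), 2 / 3)
  expect_error(secon_index(c("A")), "fewer than 2")
  expect_error(secon_index(c(2, 2)), "ordered provider sequence")
})

test_that("COC equals exhaustive pair concordance on random sequences", {
  set.seed(1203)
  for (i in 1:1000) {
    s <- random_provider_sequence()
    expect_equal(coc_index(s), oracle_pair_concordance(s), tolerance = 1e-12)
  }
})

test_that("index inequalities and order properties hold on random sequences", {
  set.seed(77)
  for (i in 1:2000) {
    s <- random_provider_sequence(max_n = 12, max_k = 5)
    N <- length(s); k <- length(unique(s))
    coc <- coc_index(s); upc <- upc_index(s); sec <- secon_index(s)
    expect_lte(coc, upc + 1e-12)
    if (k == 1) expect_equal(coc, upc)
    expect_gte(upc, 1 / k - 1e-12)
    # max of SECON over orderings of a fixed count multiset
    expect_lte(sec, (N - k) / (N - 1) + 1e-12)
    # order invariance of the count-based indices
    p <- sample(s)
    expect_equal(coc_index(p), coc)
    expect_equal(upc_index(p), upc)
  }
  # SECON attains its maximum for contiguously grouped visits,
  # and is genuinely order-dependent (witness pair)
  expect_equal(secon_index(c("A", "A", "B", "B")), (4 - 2) / (4 - 1))
  expect_false(secon_index(c("A", "B", "A", "B")) ==
                 secon_index(c("A", "A", "B", "B")))
})

test_that("replicating a visit pattern fixes UPC and drives COC to the concentration limit", {
  counts <- c(5, 3, 1)
  herfindahl <- sum((counts / sum(counts))^2)
  upcs <- vapply(1:6, function(m) upc_index(counts * m), numeric(1))
  cocs <- vapply(1:6, function(m) coc_index(counts * m), numeric(1))
  expect_true(all(abs(upcs - upcs[1]) < 1e-12))
  expect_true(all(diff(abs(cocs - herfindahl)) < 0))
})

test_that("visit sequences collapse same-day claims and respect the window", {
  cohort <- tiny_cohort()
  claims <- tiny_claims("P1",
                        c("2010-02-01", "2010-02-01", "2010-02-01",
                          "2009-12-31", "2011-05-05"),
                        c("FP01", "FP01", "FP01", "FP01", "FP02"))
  v <- build_visit_sequences(claims, cohort)
  # 3 same-day same-physician claims collapse to 1; the pre-index claim drops
  expect_identical(nrow(v), 2L)
  expect_identical(v$physician_id, c("FP01", "FP02"))

  # 6 claims on 6 days across 2 physicians: N = 6, k = 2
  claims6 <- tiny_claims("P1", sprintf("2010-03-%02d", 1:6),
                         c("FP01", "FP01", "FP02", "FP01", "FP02", "FP01"))
  v6 <- build_visit_sequences(claims6, cohort)
  expect_identical(nrow(v6), 6L)
  expect_identical(length(unique(v6$physician_id)), 2L)

  # claims for unknown patients are dropped and counted
  stray <- dplyr::bind_rows(claims6,
                            tiny_claims("P9", "2010-03-01", "FP01"))
  v7 <- build_visit_sequences(stray, cohort)
  expect_identical(nrow(v7), 6L)
  expect_identical(attr(v7, "dropped_claims"), 1L)

  # non-outpatient and non-FP/RESP claims are excluded
  mixed <- claims6
  mixed$setting[1] <- "other"
  expect_identical(nrow(build_visit_sequences(mixed, cohort)), 5L)
})

test_that("same-day visits to different physicians stay distinct, ordered by id", {
  cohort <- tiny_cohort()
  claims <- tiny_claims("P1", rep("2010-02-01", 2), c("FP02", "FP01"))
  v <- build_visit_sequences(claims, cohort)
  expect_identical(nrow(v), 2L)
  expect_identical(v$physician_id, c("FP01", "FP02"))  # stable date-then-id order
})

test_that("predominant provider classification follows the visit majority, ties to FP", {
  mk <- function(n_fp, n_sp) {
    tibble::tibble(patient_id = "P1",
                   specialty_group = rep(c("FP", "SP"), c(n_fp, n_sp)))
  }
  r1 <- classify_predominant_provider(mk(8, 2))
  expect_identical(r1$predominant_group, "FP")
  expect_equal(r1$fp_visit_share, 0.8)
  expect_identical(classify_predominant_provider(mk(5, 5))$predominant_group, "FP")
  r3 <- classify_predominant_provider(mk(1, 9))
  expect_identical(r3$predominant_group, "SP")
  expect_equal(r3$fp_visit_share, 0.1)
})

test_that("haversine distance matches closed-form values on a 6371 km sphere", {
  expect_equal(distance_km(45, -75, 45, -75), 0)
  expect_equal(distance_km(0, 0, 1, 0), 6371 * pi / 180, tolerance = 1e-6)
  expect_equal(distance_km(0, 0, 0, 180), 6371 * pi, tolerance = 1e-6)
  expect_error(distance_km(95, 0, 0, 0), "lat1")
  expect_error(distance_km(0, 200, 0, 0), "lon1")
})

test_that("median dichotomization assigns low to scores at or below the median", {
  profiles <- tibble::tibble(patient_id = sprintf("P%d", 1:4),
                             coc = c(0.2, 0.4, 0.6, 0.8),
                             n_visits = 10L)
  out <- dichotomize_coci(profiles)
  expect_identical(as.character(out$coci_category),
                   c("low", "low", "high", "high"))
  expect_equal(attr(out, "coci_median"), 0.5)

  tied <- dplyr::mutate(profiles, coc = 0.5)
  expect_true(all(dichotomize_coci(tied)$coci_category == "low"))

  few <- dplyr::mutate(profiles, n_visits = c(10L, 3L, 10L, 10L))
  expect_identical(as.character(dichotomize_coci(few)$coci_category[2]),
                   "not_assessed")
  none <- dplyr::mutate(profiles, n_visits = 2L)
  expect_error(dichotomize_coci(none), "too few visits")
})

test_that("pipeline profiles agree exactly with the generator's ground truth", {
  sim <- simulate_copd_claims(sim_config(n_patients = 400, seed = 19))
  cohort <- build_cohort(sim)
  profiles <- compute_continuity(sim$claims, cohort, sim$persons, sim$physicians)
  joined <- dplyr::inner_join(profiles, sim$truth, by = "patient_id")
  assessed <- joined$coci_category != "not_assessed"
  expect_gt(sum(assessed), 300)
  expect_equal(joined$upc[assessed], joined$true_upc[assessed], tolerance = 1e-12)
  expect_equal(joined$coc[assessed], joined$true_coc[assessed], tolerance = 1e-12)
  expect_equal(joined$secon[assessed], joined$true_secon[assessed], tolerance = 1e-12)
  # planted split agrees with truth away from the median boundary
  med <- attr(profiles, "coci_median")
  off_median <- assessed & abs(joined$coc - med) > 1e-9 & joined$expected_in_analysis
  agree <- (joined$coci_category[off_median] == "low") ==
    joined$true_low_coci[off_median]
  expect_true(all(agree))
  expect_true(all(joined$distance_km[assessed] >= 0))
})
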