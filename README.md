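# coconet

Continuity-of-care analysis for administrative health claims, built around
the physician network of newly diagnosed COPD patients.

Patients with chronic obstructive pulmonary disease are cared for by both
family physicians (FP) and respiratory specialists. When that care is
fragmented across many providers, unplanned hospital use tends to rise.
`coconet` implements, end to end, the standard claims-based workflow for
quantifying this relationship on linked administrative tables (physician
billing claims, hospital discharge abstracts, emergency-department records
and a person registry):

1. **Cohort derivation** — a validated COPD case definition (1+ billing
   claim and/or 1+ hospital discharge carrying ICD-9 491/492/496 or ICD-10
   J41–J44, prefix-matched), age and coverage eligibility rules, and
   censored 5-year follow-up.
2. **Continuity indices** over each patient's outpatient FP/specialist
   visit sequence with visit counts `N`, per-provider counts `n_j` and `k`
   distinct providers:
   - usual provider of care, `UPC = max_j n_j / N`;
   - Bice–Boxerman concentration of care,
     `COC = (Σ_j n_j² − N) / (N (N − 1))` — the probability that two
     distinct visits share a provider;
   - sequential continuity, `SECON = Σ_i 1[p_i = p_{i+1}] / (N − 1)`;
   plus the predominant provider group (FP vs specialist), the haversine
   distance to the usual provider, and a median-cut low/high COC category
   (patients with ≤ 5 visits are not assessed).
3. **Unplanned-utilization outcomes** — all-cause and COPD-related
   admissions, 30-day readmission derivation (unplanned, non-transfer,
   day 1–30 after the preceding discharge, after merging overlapping
   stays), ED visit classes, in-hospital death.
4. **Descriptive tables** with standardized differences (continuous,
   binary, and a Mahalanobis-type multi-category form).
5. **Model suite** — 12 logistic regressions (4 outcomes × unadjusted /
   model A / model B tiers) of each outcome on low vs high COC, model A
   adjusting for age, sex, ADG comorbidity score, socioeconomic status and
   rurality, model B adding the provider group. Results are odds ratios
   with Wald 95% intervals.

Because the real provincial data are privately held, the package ships a
**synthetic linked-claims generator** with known ground truth: visit counts
are heavy-tailed negative binomial, visits spread over a personal provider
pool by a symmetric Dirichlet-multinomial whose concentration parameter
dials continuity, and outcomes follow a logistic model with a **planted
low-continuity odds ratio** (default 2.25). Every pipeline stage is tested
against this ground truth.

## Worked example

```r
library(coconet)

sim <- simulate_copd_claims(sim_config(n_patients = 5000, seed = 42))
res <- run_coc_pipeline(sim)
res
#> <coc_pipeline>
#>   cohort: 5000 screened, 4847 eligible
#>   profiles: 4847, assessed for COCI: 4733 (median COC 0.462)
#>   model suite:
#> # A tibble: 12 × 7
#>    outcome           adjustment_tier exposure_or ci_low ci_high n_used converged
#>    <chr>             <chr>                 <dbl>  <dbl>   <dbl>  <int> <lgl>
#>  1 any_admission     unadjusted             2.22   1.97    2.49   4733 TRUE
#>  2 any_admission     model_A                2.34   2.08    2.64   4733 TRUE
#>  3 any_admission     model_B                2.34   2.07    2.64   4733 TRUE
#>  4 any_ed_visit      unadjusted             1.61   1.29    2.00   4733 TRUE
#> # … 8 more rows
```

The `any_admission` / `model_A` row is the headline estimate: patients in
the low-continuity half of the cohort have about 2.3 times the odds of a
hospital admission during follow-up (this replicate's planted truth is
2.25; the 95% CI covers it).
The continuity profiles and descriptive tables are plain tibbles:

```r
head(res$profiles[, c("patient_id", "n_visits", "upc", "coc", "secon", "coci_category")])
tab <- build_comparison_table(res$profiles, res$outcomes, sim$persons)
autoplot(tab)          # standardized-difference dot plot
autoplot(res$suite)    # forest plot of the 12 odds ratios
```

Individual stages are exported (`find_index_dates()`,
`apply_exclusions()`, `define_followup()`, `build_visit_sequences()`,
`coc_index()`, `upc_index()`, `secon_index()`, `count_admissions()`,
`flag_30day_readmissions()`, `classify_ed_visits()`, `std_diff_*()`,
`build_design()`, `fit_continuity_model()`), so each piece can be used or
audited on its own. `write_claims_csv()` / `read_claims_tables()` move the
linked tables through plain ISO-8601 CSV files.

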