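---
title: "Methods: claims-based continuity of care and unplanned utilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: claims-based continuity of care and unplanned utilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coconet)
```

## The scientific question

Care for chronic obstructive pulmonary disease (COPD) is shared between
family physicians (FP) and respiratory specialists. `coconet` quantifies
how concentrated a newly diagnosed patient's outpatient physician care is,
and how that concentration relates to unplanned hospital use over the five
years after diagnosis, using only the event streams found in linked
administrative claims: billing claims, hospital discharge abstracts,
emergency-department (ED) records, and a person registry.

## Cohort derivation

A patient enters the cohort at the **index date**: the earliest billing
claim or hospital discharge in the recruitment window (default 2005-04-01
to 2013-03-31) whose diagnosis code matches the COPD case definition.
Matching is prefix-based because administrative codes carry sub-digits
(`J44` matches `J44.1`). The default ICD-9 set is `{491, 492, 496}`: the
published algorithm lists "91, 492, 496", and we read "91" as a truncation
of 491 (chronic bronchitis), since 491/492/496 is the standard validated
claims triad; the literal printed set can be supplied via
`copd_case_definition()` if wanted.

Exclusions are applied in a fixed order so every excluded patient carries
exactly one reason: invalid identifier, non-resident, no insurance
coverage at the index date, COPD history before the window, then age < 35
at index. Two reading choices deserve note. First, "no coverage for the
entirety of the study" is operationalised as *coverage absent at the index
date*; coverage that lapses during follow-up is treated as the patient
moving away, i.e. a censoring event, not an exclusion — otherwise the
"moved out of province" censor could never occur. Second, patients whose
only qualifying event precedes the window cannot be assessed for coverage
at an index date they do not have, so the COPD-history reason takes
precedence for them.

Follow-up is the half-open interval `[index, end)` with
`end = min(index + 5 years, death, coverage end, study end)` (study end
defaults to 2018-03-31) and the censor reason follows that priority order
on ties. The five-year anniversary is calendar-based (Feb 29 indices roll
to Mar 1 in non-leap years). A two-year pre-index look-back is the
convention for comorbidity measurement; patients with less history are
retained with a truncated look-back, since the comorbidity input here is a
supplied integer score rather than a recomputed grouper output.

## Continuity indices

For each eligible patient we take outpatient claims by FPs and respiratory
specialists inside follow-up, collapse same-day claims to the same
physician into one visit, and order visits by date then physician id (the
date-then-id tie-break only affects the sequential index). With `N` visits,
`n_j` visits to provider `j`, and `k` distinct providers:

* **UPC** (usual provider of care) `= max_j n_j / N`,
* **COC** (Bice–Boxerman) `= (Σ_j n_j² − N) / (N (N − 1))`, the
  probability that two distinct visits drawn without replacement share a
  provider: 0 when every visit is to a different provider, 1 when a single
  provider delivers all care,
* **SECON** `= Σ_{i<N} 1[p_i = p_{i+1}] / (N − 1)`, the fraction of
  adjacent visit pairs with the same provider.

Useful inequalities, all property-tested: `COC ≤ UPC` with equality iff
`k = 1`; `UPC ≥ 1/k`; `SECON ≤ (N − k)/(N − 1)` with equality when visits
are contiguously grouped.

Patients with 5 or fewer visits are not assessed (their indices are
reported missing), mirroring the published analysis. The low/high COC
exposure splits assessed patients at the median, computed *after* that
exclusion; scores exactly at the median go to the low group, chosen
because the published low group is the larger one. The predominant
provider group is whichever specialty group received more visits, with
exact ties assigned to FP — the system's default attachment point, and
consistent with the heavily FP-weighted published split. Distance to the
usual provider (the physician with most visits, ties to the earliest
seen) is the haversine great-circle distance on a 6371 km sphere between
the patient's residence and the physician's office geolocation.

## Utilization outcomes

All outcomes are derived inside the follow-up interval. Overlapping or
nested hospital stays are merged into single episodes first, so a ward
transfer cannot masquerade as a same-day readmission. A **30-day
readmission** is an unplanned (neither elective nor transfer) admission 1
to 30 days (inclusive) after the immediately preceding episode's
discharge; day 0 is excluded as a transfer-back, and each consecutive
qualifying pair increments the count — one index stay is never chained to
multiple readmissions. "COPD-related" means the most-responsible
diagnosis matches the case-definition code sets. ED visits split into
with- and without-admission classes via their discharge linkage; scheduled
ED-to-admission events are excluded from the unplanned with-admission
count, and an admitted ED visit with no matching discharge is a logged
linkage defect counted as without admission. "Any hospital admission"
counts all admissions by default ("any cause" in the published tables);
an `unplanned_only` flag restricts to non-elective, non-transfer stays.

## Descriptive contrasts

Group tables report binned counts (0, 1–5, 6–10, >10), means ± SD, and
standardized differences: the usual pooled-SD form for continuous
variables, its binomial specialisation for flags, and for multi-category
variables a Mahalanobis-type distance over the first `L−1` categories
using the averaged multinomial covariance. The multi-category form reduces
exactly to the binary form at `L = 2` (tested to 1e-12) and is checked
against an independently coded loop implementation. Categories empty in
both groups are dropped — they carry no information and would make the
covariance singular. Identical groups give 0; degenerate zero-variance
contrasts return `Inf` with a warning rather than an error, so a full
table can still be rendered.

## The model suite

Twelve logistic regressions: four outcomes (any admission, any ED visit,
any 30-day readmission, ≥ 2 readmissions) by three tiers (unadjusted;
model A: age, sex, ADG comorbidity score, income quintile + composite
marginalization score, rurality; model B: model A + predominant provider
group). The exposure is the low-COC category with high as reference.
"Number of readmissions" is dichotomised at ≥ 2 so the same logistic
machinery serves all four outcomes, as the published analysis used
logistic models throughout; a negative-binomial count model is available
separately (`fit_readmission_count_model()`) as a non-primary companion.
Age enters continuously in years (the published analysis does not state a
functional form); socioeconomic status enters as both income quintile
(categorical) and the composite marginalization score (continuous), the
two components listed under "social status". Intervals are Wald,
`exp(β ± 1.96·SE)` — at these sample sizes profile-likelihood intervals
are indistinguishable and the published symmetric intervals indicate the
same choice. Complete separation is detected (via the separation warning
or an exploding exposure coefficient/standard error) and reported as
non-convergence rather than a spurious estimate. Patients censored early
by death contribute as non-events for outcomes they never had the chance
to experience; the pipeline fits plain logistic models, as published, and
the differential follow-up is visible in the cohort's censor reasons.

## The synthetic-claims generator

No public dataset accompanies this design — the source tables are held
privately — so the generator is a first-class module that emulates their
statistical structure with known ground truth:

* **Visit counts**: `N = 1 + NegBin(size 2.2, mean 36)`, calibrated once
  to the published 5-year visit distribution (simulated bins
  2.9/6.8/19.1/71.2% versus published 1.0/8.4/19.6/71.0% for 1–5, 6–10,
  11–20, >20 visits). Every patient's first visit is the index COPD claim.
* **Provider allocation**: each patient has a pool of `K = 8` physicians;
  Dirichlet(α) weights are drawn with `α = 0.159` and visits sample
  providers independently with those weights. α was solved analytically
  from the Dirichlet-multinomial pair-match probability
  `(1 + α)/(1 + Kα) = 0.51`, the published mean COC; one parameter spans
  the full COC range continuously (α → 0 gives one provider, α → ∞ a
  uniform spread), and realized mean COC ≈ 0.51, UPC ≈ 0.64 at defaults.
  Visit days are sampled without replacement over follow-up (so same-day
  collapse never changes the realized counts) and sorted; SECON ground
  truth comes from that order.
* **Predominant type**: 5.7% of patients are specialist-anchored (the
  published share); the pool slot carrying the largest visit count gets
  the patient's anchor specialty.
* **Outcomes**: any admission follows a logistic model in the *true*
  dichotomized low-COC group (a clean A/B contrast rather than the
  continuous score) plus age, sex, comorbidity, marginalization and
  rurality terms; the planted low-COC log-odds defaults to `log(2.25)`.
  Admissions beyond the first, 30-day readmission gaps, and ED visit
  counts have their own low-COC effect dials (defaults 1.3, 1.4 and 1.2 as
  rate/odds ratios, set in one calibration pass so the suite's
  outcome-level adjusted odds ratios land in the published 2.3–3.7 range —
  rate effects on counts compound nonlinearly into any-event odds); a
  `sim_config_null()` helper zeroes every dial for calibration studies.
  Emergent admissions get a linked same-day ED record, satisfying the
  ED-to-discharge referential invariant. Death and move-out are
  exponential hazards (3%/yr and 1%/yr); small planted rates of invalid
  identifiers, non-residents, coverage gaps and pre-window COPD claims
  exercise each exclusion rule.
* **Determinism**: the root seed spawns fixed per-stage sub-seeds, so one
  config and seed reproduce every table byte-for-byte.

One visible consequence of the i.i.d. allocation: adjacent visits are no
more alike than any two visits, so the generator's mean SECON equals its
mean COC (about 0.51) rather than the higher published value (0.64),
which reflects temporal clustering of same-provider visits — bursts of
specialist care during exacerbations — that the generator does not model.
The SECON *computation* is unaffected and is tested on explicit ordered
sequences.

What the generator does *not* emulate: real geography and travel patterns,
group-practice billing (each visit is attributed to an individual
physician), fee codes, seasonal exacerbation waves, disease severity and
its correlation with specialist referral, and informative censoring.
Passing tests therefore demonstrate that the pipeline's logic is correct
and that the estimator recovers a known effect under the assumed data
model — not that the published effect sizes are themselves reproduced from
real data.

## Validation design and problem sizes

The test suite checks every index against brute-force oracles (exhaustive
pair enumeration for COC on 1,000 random sequences; closed-form haversine
values; an independently coded categorical standardized difference),
verifies the published tables' internal arithmetic, and runs two
simulation studies chosen to balance statistical resolution against a few
minutes of runtime: planted-effect recovery on 20 replicates of 20,000
patients (mean recovered odds ratio within 10% of 2.25 and Wald coverage
of the truth), and null calibration of all 12 suite models on 10
replicates of 6,000 patients (the share of intervals covering 1 should be
near 95%). With 20 replicates the nominal-coverage estimate is coarse —
each replicate is worth 5 percentage points, and a perfectly calibrated
interval will cover in all 20 replicates about a third of the time.

Numerical conventions worth knowing: all intervals on dates are half-open
`[start, end)`; COC and SECON are undefined (`NA`) below 2 visits and all
indices are reported missing at ≤ 5 visits; the COC median split is
`≤ median → low`; empty provider pools, negative counts, probabilities
outside `[0,1]` and death-before-index raise immediate errors naming the
offending field.

## Limitations

The comorbidity score is a supplied integer stand-in for a proprietary
diagnostic grouper; marginalization covariates are consumed as precomputed
area-level scores; geolocations are inputs, not geocoded postal codes.
The case definition's published validation (sensitivity 85%, specificity
78.4%) is cited context, not recomputed. Continuity is measured over FP
and respiratory-specialist claims only, so care from other specialties is
invisible to the indices, and physicians working in group models are
treated as individuals.
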