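Package: coconet
Title: Continuity-of-Care Analysis for Administrative Health Claims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying physician continuity of care in
    administrative-claims cohorts of newly diagnosed chronic obstructive
    pulmonary disease (COPD) patients. Derives an inception cohort from
    linked billing-claim, hospital-discharge, emergency-department and
    registry tables; computes the usual-provider-of-care (UPC),
    Bice-Boxerman concentration-of-care (COC) and sequential-continuity
    (SECON) indices over each patient's outpatient physician network;
    derives unplanned-utilization outcomes including 30-day readmissions;
    builds descriptive comparison tables with standardized differences; and
    fits the unadjusted and confounder-adjusted logistic model suite
    relating low continuity to utilization. Includes a synthetic linked
    claims generator with known ground-truth continuity structure and a
    planted continuity-outcome effect for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    generics,
    geosphere,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
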