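Package: secondcancer
Title: Excess Risk of Second Primary Cancers in Breast Cancer Survivor Cohorts
Version: 0.1.0
Authors@R:
    person("Registry", "Methods Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the excess incidence of second primary
    cancers in a cohort of women treated for early invasive breast cancer,
    relative to external (general-population) reference rates. Implements
    eligibility filtering and Lexis person-time splitting by attained age,
    calendar year and deprivation fifth; standardised incidence ratios and
    absolute excess rates with exact Poisson (Garwood) intervals; observed and
    expected cumulative risks under competing events via a discrete annual
    two-step estimator; stratified Poisson rate-ratio regression for adjuvant
    treatment exposures with a pre-specified significance decision rule; and
    attributable-fraction accounting of treatment-associated excess cancers.
    A synthetic cohort and reference-rate generator with known ground truth
    (piecewise-constant cause-specific hazards, exact inverse-transform
    sampling) makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    survival
Config/testthat/edition: 3
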