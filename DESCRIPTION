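Package: extarm
Title: External Control Arm Comparisons for Line-of-Therapy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for externally controlled comparisons of a single-arm
    trial cohort against a real-world physician's-choice cohort observed as
    repeated lines of therapy (LOTs). Provides eligibility-based assembly of
    LOT-level analysis sets, neighbour-rule imputation of block-missing
    metastatic-site covariates, propensity-score ATT (average treatment
    effect among the treated) inverse-probability weighting with
    standardized-mean-difference balance diagnostics, and weighted and
    covariate-adjusted effect estimation (response odds and rate ratios,
    weighted Kaplan-Meier curves, Cox hazard ratios) with patient-clustered
    robust variance. A synthetic two-cohort generator with gamma-frailty
    proportional-hazards outcomes makes every stage testable without access
    to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    tools,
    survival,
    sandwich,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
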