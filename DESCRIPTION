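Package: szvalid
Title: External Validation of Prognostic Models for Seizure Recurrence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for externally validating Cox proportional-hazards
    prognostic models of seizure recurrence after a first unprovoked
    seizure. Provides cohort ingestion and eligibility filtering, a
    synthetic-cohort generator with known hazard-ratio truth for four study
    profiles, Cox fitting with optional stratification by study, Harrell's
    c-index discrimination and calibration checks, centile-based risk
    grouping transported across cohorts, five schemes for a covariate that
    is missing from an entire validation dataset, and conditional 12-month
    recurrence-risk curves with confidence intervals from a windowed
    Greenwood variance and the time at which forward risk falls below a
    regulatory threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
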