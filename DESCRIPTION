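Package: ipfclaims
Title: Treatment Patterns, Weighting, and Cost Models for Antifibrotic Claims Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for claims-based comparative studies of the two antifibrotic
    therapies for idiopathic pulmonary fibrosis. Builds new-user cohorts from
    administrative enrollment, pharmacy, and medical claim tables; constructs
    medication coverage timelines with titration adjustment and overlap
    appending; computes proportion-of-days-covered adherence, gap-based
    discontinuation, switching, persistence, and re-initiation; estimates
    inverse-probability-of-treatment weights with standardized-mean-difference
    balance diagnostics; aggregates all-cause and respiratory-related
    utilization and costs per patient per month or year with CPI inflation; and
    fits weighted logistic, Cox, and gamma-log-link cost models with recycled
    predictions and bootstrap confidence intervals. Includes a synthetic claims
    generator with known ground truth for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    survival,
    sandwich,
    ggplot2,
    generics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
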