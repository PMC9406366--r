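Package: sbce
Title: Identify Second Breast Cancer Events in Administrative Health Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a rule-based algorithm for identifying second breast
    cancer events (SBCEs; local, regional or distant recurrence, or a new
    primary breast cancer) in linked administrative health data, together
    with its validation apparatus.  Four configurable criteria (death from
    breast cancer, procedure with associated diagnosis, systemic treatment,
    radiotherapy) are applied to dated, coded utilization records outside a
    180-day post-diagnosis washout window.  Includes diagnostic-agreement
    statistics against a reference standard (sensitivity, specificity,
    predictive values, Cohen's kappa with the Fleiss large-sample interval,
    and prevalence-adjusted bias-adjusted kappa), stratified
    validation-sample design calculations, and a synthetic
    administrative-cohort generator with known ground truth for end-to-end
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    yaml,
    ggplot2,
    generics,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
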