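Package: oxbalance
Title: Oxidative Balance Score Construction and Serum Uric Acid Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the 20-component Oxidative Balance Score (OBS) from
    dietary and lifestyle exposures using fixed or sex-stratified
    tertile cutoffs, applies a complete-case exclusion pipeline with a
    hyperuricemia case definition for serum uric acid, and estimates
    quartile-based linear and logistic associations with subgroup and
    interaction analyses. Ships a synthetic NHANES-like cohort
    generator with a known exposure effect so every stage of the
    pipeline is testable without external data, plus
    publication-style baseline and association table formatters.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
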