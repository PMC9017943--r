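Package: eprflow
Title: Data Management for Multi-Center Electronic Pharmacy Record Extracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Cleans and standardizes multi-center electronic pharmacy record
    (EPR) extracts of injectable cancer-drug administrations, applies
    patient-level exclusion rules with flow-chart accounting, infers missing
    disease stage and treatment line from administration histories, audits
    inference quality by random sampling with exact (Clopper-Pearson)
    binomial confidence intervals and finite-population sample sizing, and
    assesses completeness, coverage and representativeness of the resulting
    cohort against a national reference. Ships a synthetic EPR generator with
    retained ground truth so every step of the pipeline can be validated
    end-to-end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
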