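Package: pimscreen
Title: Screening Older-Adult Prescriptions for Potentially Inappropriate
    Medications with the STOPP Version 3 Criteria
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule engine that evaluates all 133 explicit STOPP version 3
    criteria against structured older-adult inpatient records (ATC level-5
    coded medication orders, coded clinical conditions and laboratory values),
    producing per-patient potentially-inappropriate-medication (PIM) flags
    with a tri-state triggered / not-triggered / not-evaluable contract.
    Companion stages cover Charlson Comorbidity Index scoring, prevalence and
    tally bookkeeping, crude odds ratios from two-by-two tables with Woolf
    confidence intervals, a p < 0.25 bivariate screen feeding a multivariable
    logistic model of PIM exposure, single-proportion sample-size
    calculations, and a deterministic synthetic cohort generator so that the
    whole pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
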