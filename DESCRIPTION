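Package: excesscohort
Title: Observed Versus Expected Psychometric Scores in an Exposed Cohort
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Indirect standardization of psychometric scale scores for an
    exposed cohort against an age-by-gender stratified reference sample.
    Scores the 10-item Hopkins Symptom Checklist (HSCL-10) and a 4-item
    Crisis Support Scale with their missing-item rules, derives per-person
    expected scores and expected caseness from exact (gender, age) reference
    strata, computes excess statistics (mean difference, ratio of means,
    standardized effect size, excess caseness above the HSCL-10 cut-off of
    1.85), and attaches bootstrap-percentile confidence intervals from a
    doubly-stratified bootstrap in which the expectation table is rebuilt
    inside every resample. Includes a latent-trait ordinal generator that
    emulates both tables for testing and simulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
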