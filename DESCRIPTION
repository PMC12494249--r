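Package: hba1cvar
Title: Within-Individual Variation of HbA1c from Longitudinal Primary-Care Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the total within-individual coefficient of
    variation (CV_T) of glycated haemoglobin (HbA1c) from longitudinal,
    EHR-style laboratory records. Provides a seeded synthetic-cohort generator
    that emulates routinely collected primary-care HbA1c data (including its
    characteristic recording errors), a reproducible cleaning cascade with
    per-rule accounting, variance-components estimation of CV_T by REML and
    method-of-moments with crude and log-scale variants, IFCC/NGSP unit
    conversion and its effect on the CV, stratified and cross-classified
    subgroup estimation, empirical first-to-second result transition matrices
    with minimal-clinically-important-difference exceedance probabilities,
    analytic repeat-test decision probabilities under the normal measurement
    model, and a config-driven end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    readr,
    jsonlite
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
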