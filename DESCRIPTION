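Package: ptsdemr
Title: Rule-Based PTSD Case Definitions for Primary Care Electronic
    Medical Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for building and validating rule-based posttraumatic
    stress disorder (PTSD) case definitions in multi-table primary care
    electronic medical record (EMR) extracts.  Implements four case
    definitions combining ICD-9-CM diagnosis codes from the health
    condition, billing and encounter diagnosis tables, ATC medication
    codes, and lexicon-based detection of PTSD mentions in short
    diagnostic text; agreement statistics (sensitivity, specificity,
    predictive values, accuracy) with exact binomial (Clopper-Pearson)
    confidence intervals; small-cell suppression for disclosure control;
    exact binomial prevalence estimation; and a synthetic EMR generator
    with a simulated dual-reviewer chart-review process so the whole
    pipeline can be exercised without access to real patient data.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
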