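Package: cakiscore
Title: Updating and Validating a Points-Based Risk Score for Cisplatin-Induced
    Acute Kidney Injury
Version: 0.1.0
Authors@R:
    person("Kaz", "Developer", email = "dev@example.org", role = c("aut", "cre"))
Description: Tools for validating and updating points-based clinical risk
    scores for cisplatin-induced acute kidney injury (C-AKI). Implements the
    Motwani points table and its logistic anchor, outcome classification by
    creatinine rise with AKIN staging, renal-function formulas
    (Cockcroft-Gault, CKD-EPI), a univariate screening battery (Fisher's exact
    test, Woolf odds-ratio intervals, Mann-Whitney U, per-unit logistic odds
    ratios), logistic recalibration-and-extension model updating with AIC
    candidate scanning and score-point assignment, a calibration and
    discrimination metric battery with bootstrap intervals and
    optimism-corrected C-statistics, categorical net reclassification
    improvement, integrated discrimination improvement and decision curve
    analysis, plus a seeded synthetic-cohort generator so the whole pipeline
    is testable without patient-level hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
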