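Package: cipdus
Title: Construction and Evaluation of the CIP-DUS Digital Ulcer Risk Score
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating additive clinical risk scores
    of the CIP-DUS family (clinical features, imaging and patient history for
    the prediction of digital ulcers in systemic sclerosis). Implements
    per-feature diagnostic assessment (odds ratios with Haldane-Anscombe
    continuity correction, Woolf confidence intervals, Fisher exact tests,
    sensitivity and specificity), univariate logistic regression with k-fold
    cross-validated AUC, the cvAUC-to-weight rule and the canonical CIP-DUS
    weight schemes (with and without the Doppler-ultrasound and fluorescence
    optical imaging components), ROC analysis with DeLong comparison of
    correlated AUCs, Youden-index cutoff selection, Hosmer-Lemeshow
    calibration, net reclassification improvement and integrated
    discrimination improvement, plus a synthetic-cohort generator that
    reproduces the outcome-conditional feature prevalences of the published
    development cohort so that every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
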