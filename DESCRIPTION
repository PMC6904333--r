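Package: pairsig
Title: Rank-Based Gene-Pair Prognostic Signatures for Censored Survival Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds, applies and evaluates prognostic signatures made of
    within-sample gene-pair order indicators for survival-annotated
    expression data. A pair feature scores 1 when the first gene's
    abundance is strictly below the second's inside the same sample, so
    signatures transfer across platforms and abundance units (FPKM, RPM)
    without normalization and can score a single profile in isolation.
    The pipeline covers differential-expression candidate nomination,
    pair construction and constancy filtering, familywise-error-controlled
    log-rank screening, L1-penalized Cox signature fitting with
    cross-validated penalty selection, nearest-neighbor time-dependent
    ROC cutoff selection and AUC evaluation, Kaplan-Meier/log-rank/Cox
    risk-group evaluation with subgroup analysis, a clinically adjusted
    composite score with stepwise covariate selection, and a two-cohort
    synthetic data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    survival,
    glmnet,
    limma,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
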