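Package: faersignal
Title: Pharmacovigilance Signal Detection and Time-to-Onset Analysis for
    FAERS-Style Spontaneous Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for disproportionality-based safety signal
    detection in spontaneous adverse-event reporting data shaped like the
    FDA Adverse Event Reporting System (FAERS) quarterly ASCII releases.
    Reads the "$"-delimited DEMO/DRUG/REAC/THER/OUTC/INDI tables,
    de-duplicates case versions, normalizes drug names to ATC, and flags
    cases by MedDRA Preferred Term. Computes four disproportionality
    statistics per drug-event pair (reporting odds ratio, proportional
    reporting ratio with Pearson chi-square, unshrunk empirical Bayes
    geometric mean, and the Bayesian confidence propagation neural network
    information component) with their interval bounds and signal criteria;
    screens risk factors by univariate logistic regression with Bonferroni
    correction, LASSO selection, and multivariate logistic regression; and
    characterizes onset timing by Weibull shape-parameter failure-type
    classification and rank-sum subgroup comparison. A seeded synthetic
    FAERS-corpus generator with known injected signals makes every stage
    testable without access to the live database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vctrs,
    withr
Suggests:
    fitdistrplus,
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
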