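Package: codelcall
Title: Predicting Chromosome 1p/19q Codeletion from Bulk RNA Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements and compares five expression-based classifiers for
    chromosome 1p/19q codeletion status in glioma: a top-scoring-pair rule,
    per-sample arm enrichment scores from a kernel-CDF weighted random walk,
    a nearest shrunken centroid classifier with cross-validated threshold
    selection, partial least squares discriminant analysis, and positional
    Gaussian smoothing of genomically ordered expression. Includes the shared
    evaluation machinery (confusion metrics, ROC/AUC, chi-square tests,
    hierarchical two-branch assignment) and a synthetic-data generator that
    emulates arm-level one-copy-loss expression shifts with per-gene baselines,
    Gaussian noise and gene-wise batch effects, so the full comparison runs at
    desk scale without external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
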