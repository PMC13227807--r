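Package: seromiR
Title: Serum miRNA Diagnostic Panel Workflow for Alzheimer's Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible workflow for building and evaluating serum
    microRNA diagnostic panels for Alzheimer's disease from
    feature-by-sample expression matrices. Provides seeded synthetic
    cohort generation with realistic covariate imbalance and correlated
    feature clusters, quantile normalization and variance filtering,
    covariate-adjusted empirical-Bayes moderated differential expression
    with Benjamini-Hochberg false discovery control, directionality
    set-statistics and weighted signature scores, univariate covariate
    diagnostics (Youden thresholds, cross-validated transfer, Cramer's V,
    partial rank correlations), correlation-network clustering with module
    eigengenes, cluster-constrained forward panel selection inside nested
    cross-validation with one-standard-error panel sizing, and penalized
    logistic classifier evaluation with calibration, operating points, and
    decision-curve analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    limma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    e1071,
    jsonlite,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
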