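Package: cassandra
Title: Cassandra Lymph-Node Malignancy Scoring and Synthetic Cohort Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Cassandra family of axillary lymph-node malignancy
    scores from intraoperative ultrasound and shear-wave elastography features:
    feature binarization at calibrated cut-offs, the integer-weighted LNMS A/B/C
    scores, and the two-tier Cassandra decision rule. Provides the evaluation
    statistics used to build and validate such scores (ROC/AUC with Hanley-McNeil
    standard errors, Gini index, maximum Kolmogorov-Smirnov statistic, Youden and
    sensitivity-constrained cut-point selection, tie-corrected Mann-Whitney z,
    Spearman and pooled within-groups correlations), first-principles linear
    discriminant and naive Bayes baselines with leave-one-out cross-validation,
    an end-to-end study pipeline, and a Gaussian-copula generator of synthetic
    cohorts with mixed binary-continuous features calibrated to published
    group-conditional marginals and within-group correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    MASS,
    e1071,
    optparse,
    withr
Config/testthat/edition: 3
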