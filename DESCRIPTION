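Package: octanomaly
Title: Local-Region Anomaly Detection and Localization for Retinal OCT Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: One-class anomaly detection and localization for retinal optical
    coherence tomography (OCT) B-scans. Healthy scans are embedded as grids of
    local-region feature vectors by a convolutional backbone; test regions are
    scored by average k-nearest-neighbour distance against a nominal bank
    (optionally compressed by a greedy k-center coreset), by per-position
    multivariate Gaussian Mahalanobis fields, or by gallery-retrieval pooled
    kNN. Image-level decisions take the maximum region score; heat maps render
    region scores at pixel resolution. Includes center-loss feature adaptation
    with elastic-weight-consolidation regularization, a seeded synthetic OCT
    B-scan generator with ground-truth anomaly masks, and evaluation metrics
    (ROC-AUC, F1, accuracy, sensitivity, specificity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    EBImage,
    png,
    tiff,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jpeg,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
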