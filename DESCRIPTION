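Package: ddnet
Title: Joint Inference of Common and Differential Dependency Networks from
    Multi-Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint estimation of common and rewired (differential) network
    structure between two biological conditions by per-node fused-Lasso
    regressions over a layered Gaussian graphical model. Supports
    user-specified allowed-predictor constraints (omics layers, directional
    regulator-effector priors, per-edge masks) and per-edge penalty matrices,
    a block coordinate descent solver with exact closed-form pairwise
    updates, a multi-layer scale-free network simulator, precision/recall/F1
    and partial-ROC evaluation of recovered edge sets, and hyperparameter
    tuning by repeated cross-validation with the one-standard-error rule.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    parallel
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
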