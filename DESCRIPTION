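Package: esanet
Title: Network Analysis of Emotion Regulation Strategies and Symptom Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Psychometric network analysis of six emotion-regulation
    strategies and sixteen depression and anxiety symptoms. Estimates
    regularized partial-correlation networks (graphical lasso selected by
    the extended Bayesian information criterion) with walktrap community
    detection for exploratory graph analysis, mixed graphical models over
    continuous strategy sum-scores and ordinal symptom items via nodewise
    cross-validated lasso regressions, node strength and bridge-strength
    centrality with case-dropping bootstrap stability (CS-coefficient),
    and expected symptom activity: a clamped Gibbs simulation that sweeps
    each strategy over its sum-score range under minimum, median, and
    maximum background scenarios. Includes a calibrated synthetic
    item-response generator for the 38-item RESS, PHQ-9, and GAD-7.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    Matrix,
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
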