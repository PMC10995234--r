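Package: coughmotion
Title: Motion-Based Cough Detection from Tri-Axial Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for evaluating time-domain features of
    tri-axial accelerometry for cough detection. Provides a synthetic
    cohort generator emulating short chest-worn accelerometer recordings
    of cough and non-cough activity, band-pass preprocessing and sliding
    window segmentation, 43 time-domain features including approximate
    entropy, 11 feature-importance ranking methods (tree-model gain and
    Gini importance, first principal component loadings, leave-one-out,
    permutation importance, recursive feature elimination at four sizes,
    and Spearman correlation), and evaluation of top-k logistic
    classifiers under subject-record-split and leave-one-subject-out
    protocols with the full set of confusion-matrix metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    glmnet,
    xgboost,
    rpart,
    randomForest,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
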