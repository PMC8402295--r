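Package: TriStageFS
Title: Tri-Stage Hybrid Filter-Wrapper Feature Selection with Binary
    Whale Optimization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Feature selection for high-dimensional classification tables
    such as microarray gene-expression matrices. Stage 1 ranks features
    with an ensemble of four filters (mutual information, chi-square,
    ReliefF, and a within-class variance score), pools the top-ranked
    features, scores each one individually with three classifiers, and
    truncates the accuracy-sorted list at a cross-validated plateau.
    Stage 2 removes redundant features by Pearson-correlation pruning and
    truncates again. Stage 3 searches subsets of the surviving features
    with a binary Whale Optimization Algorithm wrapped around a
    k-nearest-neighbour classifier, trading cross-validated error against
    subset size. Includes dataset readers (CSV, ARFF), class-wise mean
    imputation, standardize-then-normalize preprocessing, a synthetic
    generator with planted informative, redundant and noise features, and
    evaluation utilities (stratified cross-validation reports, one-sample
    t-test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    e1071,
    xgboost,
    foreign,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
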