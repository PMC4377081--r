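Package: autoridge
Title: Ridge Regression with Automatic Shrinkage Selection for
    High-Dimensional Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits linear and logistic ridge regression models to
    genome-scale SNP genotype data (minor-allele counts) where the number
    of predictors far exceeds the number of observations. The shrinkage
    parameter is chosen semi-automatically by matching the effective
    degrees of freedom for variance of the ridge fit to the number of
    principal components entering a Hoerl-Kennard-Baldwin-style
    estimator, avoiding cross-validation. Includes closed-form linear
    ridge through the eigendecomposition of the design, a cyclic
    coordinate-descent (CLG) solver for penalised logistic regression,
    position-based SNP thinning, evaluation metrics (prediction squared
    error, classification error, Brier score, ROC), univariate-selection
    and cross-validated-ridge baselines, a bias-variance decomposition of
    prediction error, and a haplotype-pool simulator of linked SNP panels
    with continuous and binary phenotype models for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    pROC
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
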