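Package: gpdeep
Title: Genomic Prediction with Bayesian Regression, Kernel Methods and
    Recurrent Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Whole-genome regression and machine-learning models for genomic
    selection in outcrossing plants: Gibbs samplers for the Bayesian alphabet
    (Bayesian ridge regression, Bayesian LASSO, Bayes A, Bayes B, Bayes Cpi),
    GBLUP and Gaussian-kernel RKHS prediction via mixed-model equations,
    AI-REML variance components with narrow- and broad-sense heritability
    ratios, Bayesian-regularized feed-forward networks trained by
    Levenberg-Marquardt with evidence updates, LSTM regression on SNP dosage
    sequences (Tanh/ReLU state activations, mini-batch grid), an iterative
    back-solving algorithm that converts predicted genetic values into
    per-SNP effects for QTL discovery, a repeated 90/10 cross-validation
    harness with Tukey-Kramer model comparison, and a synthetic
    genotype/trait generator with known truth for parameter-recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
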