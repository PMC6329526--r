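Package: blore
Title: Bayesian Multiple Logistic Regression for Case-Control GWAS
Version: 0.1.0
Authors@R: person("B-LORE", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fine-mapping and meta-analysis of case-control genome-wide
    association studies with multiple logistic regression. Per-study summary
    statistics are computed with a quasi-Laplace approximation of the
    L2-regularized logistic likelihood (mode and precision of the regularized
    fit), combined across studies by Gaussian pooling, and used to estimate
    spike-and-slab hyperparameters by empirical Bayes. Posterior inclusion
    probabilities per SNP and causal probabilities per locus are obtained by
    exhaustive enumeration of causality configurations. Includes a
    liability-threshold phenotype simulator with LD-structured synthetic
    genotypes, Oxford GEN/SAMPLE input and output, and benchmark metrics
    (recall, precision, calibration of posterior inclusion probabilities).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
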