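Package: covscreen
Title: Machine-Learning Covariate Screening Benchmark for Population PK Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation benchmark for fast covariate screening in population
    pharmacokinetic (PopPK) models. Simulates concentration-time data from a
    one-compartment oral model with log-normal inter-individual variability and
    clearance-only covariate effects across a grid of scenarios varying
    covariate counts, correlation, effect size, and sampling sparsity;
    estimates the base nonlinear mixed-effects model by Laplace approximation
    and derives empirical Bayes estimates (EBEs) of clearance with
    eta-shrinkage; scores covariates by normalized permutation importance from
    random-forest, support-vector, and neural-network regressors; selects
    covariates by top-M, order-of-importance, and minimum-of-importance rules
    as well as a stepwise covariate modeling (SCM) comparator with
    forward-inclusion/backward-elimination likelihood-ratio tests; and
    evaluates selections with confusion counts, F1, ROC curves, and AUROC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ranger,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
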