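Package: dgvbayes
Title: Bayesian-Alphabet Genomic Prediction for Multi-Breed Cattle Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome regression for direct genomic value (DGV) prediction
    in admixed, multi-breed populations. Implements single-site Gibbs samplers
    with Metropolis-Hastings variable inclusion for the Bayesian alphabet
    (BayesA, BayesB, BayesC, BayesCpi), genotype quality control and encoding,
    contemporary-group phenotype pre-correction, bootstrap training/validation
    evaluation with realized-accuracy standardization, and a multi-breed
    synthetic-data generator with breed-divergent allele frequencies,
    half-sib family structure and configurable trait architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
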