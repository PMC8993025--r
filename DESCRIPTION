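Package: grmcv
Title: Graded Response Model Calibration, Scoring and Predictive
    Cross-Validation
Version: 0.1.0
Authors@R:
    person("grmcv", "developers", email = "grmcv@example.org",
           role = c("aut", "cre"))
Description: Calibration and scoring of the unidimensional graded response
    model (GRM) for ordinal (Likert) test responses, with two calibration
    routes (Bock-Aitkin marginal maximum likelihood EM, and a regularized
    fully-Bayesian hierarchical model sampled by Hamiltonian Monte Carlo),
    four ability-scoring estimators (maximum likelihood, Warm-type weighted
    likelihood, marginal maximum likelihood, and expected-a-posteriori under
    a truncated normal prior), and an uncertainty-aware K-fold predictive
    deviance metric for comparing calibration-by-scoring pairings.  Includes
    seeded generators for synthetic item banks and response matrices so the
    full pipeline can be exercised without access to any proprietary
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
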