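Package: dyadmnl
Title: Multilevel Multinomial Models for Dyadic Behavioral Observations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Bayesian multilevel multinomial logistic regression for directed
    dyadic behavioral observations, such as naturalistic records of
    child-to-child social behavior. Events are categorical draws over K
    behavior categories with a fixed reference category; correlated
    individual-level (and optionally household-level) random effects for the
    initiator and recipient roles are given scaled LKJ-Cholesky priors in a
    non-centered parameterization and sampled with a built-in No-U-Turn
    Hamiltonian Monte Carlo sampler. Includes WAIC model comparison with
    Akaike-style weights, recomposition of random-effect correlation
    matrices, predicted-probability scenarios and contrasts, age-trend
    labelling, dyad-level descriptives, and a synthetic-community generator
    with known ground truth for simulation-based validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
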