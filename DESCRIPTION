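Package: gibbsrasch
Title: Data-Augmentation-Free Gibbs Sampling for the Extended Marginal Rasch Model
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian inference for the (extended) marginal Rasch model
    without data augmentation.  The manifest distribution of a binary
    response pattern is parameterized by item easiness parameters and a
    sequence of score parameters; all full conditional distributions are
    scaled Beta prime distributions that can be sampled exactly, so the
    cost of one Gibbs iteration is independent of the number of
    respondents.  Includes elementary symmetric function kernels,
    expected-a-posteriori ability estimation on the exp(theta) scale via
    the Dutch identity, monotonicity-constrained sampling of the score
    parameters, extensions to non-equivalent groups anchor test (NEAT)
    designs and polytomous items with fixed integer scoring weights,
    synthetic data generation, and convergence diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
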