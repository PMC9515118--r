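Package: rdurisk
Title: Hierarchical Bayesian Rank-Dependent Utility Models for Binary
    Lottery Choice
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for structural modelling of risk preferences from
    multiple-price-list (MPL) binary lottery-choice experiments with
    within-subject treatment conditions (e.g. brain-stimulation sessions).
    Implements constant relative risk aversion utility, one-parameter
    probability weighting families (linear, Kahneman-Tversky, Prelec),
    rank-dependent lottery valuation and a Luce-form stochastic choice
    rule; a generative simulator of hierarchical subject populations with
    condition-specific parameter shifts; a Hamiltonian Monte Carlo
    estimator for the hierarchical model with non-centered
    parameterization, bounded-parameter transforms and convergence
    diagnostics; WAIC and PSIS-LOO model comparison; posterior predictive
    choice-accuracy checks; and Savage-Dickey Bayes factors with 89%/95%
    credible intervals for the condition effects.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
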