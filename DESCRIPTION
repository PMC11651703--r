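Package: riskconform
Title: Utility-Based and Heuristic Models of Socially Situated Risky Choice
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical Bayesian modelling of risky choice under social
    influence. Implements a family of nested choice models -- a power-utility
    softmax model of solo gambling, an other-conferred-utility (OCU) extension
    for trials where the choices of social others are displayed, a pure
    follow/oppose heuristic model, and a hybrid simplex mixture of the
    utility-based and heuristic routes. Provides the gambling-task generator
    (lottery menus adapted from the Holt-Laury elicitation design), a
    synthetic-cohort simulator with behavioral exclusion rules, hierarchical
    MCMC estimation via JAGS with group-difference parameters and
    convergence diagnostics, integrated-BIC model comparison, parameter- and
    model-recovery protocols, model-agnostic conformity metrics, and a
    nonparametric pooled-bootstrap testing framework with robust (skipped)
    correlations and default-prior Bayes factors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
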