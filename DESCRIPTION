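Package: stressrisk
Title: Hierarchical Bayesian Prospect-Theory Analysis of Risky Choice Under
    Acute Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for dissociating risk attitudes, loss aversion and choice
    consistency in risky monetary decision-making under acute stress. Provides
    a prospect-theory value and softmax choice model, hierarchical Bayesian
    estimation (compiled adaptive MCMC) of condition and cortisol-covariate
    effects across a two-day within-subject design, convergence diagnostics
    and credible-interval utilities, a generator for the 150-trial
    gain-loss/gain-only choice task, a synthetic-cohort simulator with
    group-specific salivary-cortisol trajectories for parameter-recovery
    validation, cortisol preprocessing (modified-log change scores, outlier
    exclusion), and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
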