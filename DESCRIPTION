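Package: mdprl
Title: Models of Multi-Dimensional Probabilistic Reward Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and likelihood-based comparison of learning models for a
    multi-dimensional probabilistic reward-learning task in which agents
    configure three-dimensional stimuli and receive Bernoulli reward feedback
    governed by a hidden rule over 1-3 relevant feature dimensions. Implements
    the task's combinatorial structure and reward law, a feature-based
    reinforcement-learning model with value decay, an exact Bayesian
    rule-learning model, a family of serial hypothesis-testing models
    (random-switch, value-based, and published variants) with exact
    forward-filter likelihoods over latent hypothesis states, maximum-likelihood
    fitting with multiple restarts, leave-one-game-out cross-validation,
    model-comparison and mechanism-contribution metrics, synthetic cohort
    generation, and parameter/model-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
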