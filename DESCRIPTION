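Package: dynaprl
Title: Simulation and Computational Modelling of Dynamic Probabilistic
    Reversal Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying asymmetric learning from wins and losses
    in two-armed bandit tasks with reversing reward contingencies. Provides
    a trial-level simulator for dynamic probabilistic reversal learning
    (dynaPRL) environments with high-, low- and no-contrast reward blocks;
    four reinforcement-learning models (standard delta-rule, averaged
    reward-prediction-error, global-reward-state, and a five-parameter
    model with valence-specific learning and value-decay rates) in both
    likelihood and generative mode; per-session maximum-likelihood fitting
    with multi-restart and BIC model comparison; two-group hierarchical
    Bayesian estimation of the five-parameter model with directed Bayes
    factors; model-independent win-stay/lose-shift and perseveration
    analyses; and trial-by-trial latent-state analyses linking unsigned
    averaged prediction errors and reward history to stay/shift behavior.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
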