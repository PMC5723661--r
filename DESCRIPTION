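Package: flexlearn
Title: Flexible Learning-Rate Models for Probabilistic Reward Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a two-armed probabilistic reward task with easy
    (fixed reward probability) and hard (stepwise reversal) runs, and fits a
    flexible learning model: a discretized joint Bayesian filter over a
    volatility parameter, a trial-varying learning rate and the belief that
    one option is the more rewarding, inferred from observed choices and
    rewards. Includes fixed-rate and prediction-error-scaled reinforcement
    learning baselines, softmax choice models estimated by expectation-
    maximization, two-fold cross-validated BIC model comparison, behavioral
    analyses of reward-modulated learning (choice repetition, dynamic choice
    regression, learning-rate/repetition correlation), and a model-based
    fMRI design stage (parametric modulators, within-group
    orthogonalization, canonical HRF convolution, per-voxel GLM and group
    t-tests) validated by effect recovery on synthetic BOLD signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    dplyr,
    readr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
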