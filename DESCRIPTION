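Package: advicehgf
Title: Hierarchical Bayesian Models of Social Learning from Volatile Advice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and model-based analysis of an adviser-player
    economic game in which a player predicts a binary lottery outcome from
    a probabilistic visual cue and the recommendation of an adviser whose
    incentives, and hence intentions, change over time. Provides a
    synthetic-data generator for the task (adviser strategies, score
    dynamics, rating probes, and a blindfolded-adviser control condition),
    trial-wise belief-updating models (three-level binary Hierarchical
    Gaussian Filter, a reduced no-volatility variant, and Rescorla-Wagner),
    response models mapping beliefs to choices with fixed or
    volatility-coupled decision noise, maximum-a-posteriori model inversion
    with Laplace approximation of the log model evidence, random-effects
    Bayesian model selection with family-level inference, and a
    parameter and model recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    pracma
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
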