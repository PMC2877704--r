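Package: msfr
Title: Bayesian Multispecies Functional Response Models for Generalist
    Predators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Holling-family single- and multi-species functional
    response models to prey-delivery count data from generalist predators,
    using a negative-binomial observation model and a component-wise
    random-walk Metropolis-Hastings sampler with burn-in proposal tuning.
    Includes posterior summaries, cumulative-mean convergence diagnostics,
    randomized probability-integral-transform predictive checks, a
    graphical-equilibrium analysis of logistic prey recruitment against
    predator-induced mortality (including the posterior probability of a
    low-density "predator pit" equilibrium), and a synthetic-data generator
    emulating a hen harrier diet study with three prey species.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
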