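Package: snnferl
Title: Spiking Neural Network Realization of Free-Energy-Based Reinforcement Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates leaky integrate-and-fire networks whose pseudo-free-energy
    approximates the negative state-action value of a restricted Boltzmann
    machine (RBM), trained with SARSA temporal-difference updates. Provides the
    exact RBM free-energy reference, three spike-based free-energy estimators
    (average-rate, batch-instantaneous and sequential-instantaneous), a working
    memory layer with circular-Gaussian recurrent weights and topographically
    constrained contrastive-divergence pretraining, three maze tasks of
    increasing partial observability with synthetic digit observations, and the
    equivalence analyses relating the spiking network to its RBM counterpart.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
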