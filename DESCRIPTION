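Package: pnnsim
Title: Conductance-Based Neuron Models for Perineuronal-Net Degradation Studies
Version: 0.1.0
Authors@R: person("pnnsim", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Multicompartment conductance-based neuron simulation and analysis
    toolkit for studying how parameter changes associated with perineuronal
    net (PNN) degradation -- specific membrane capacitance, ion-channel
    conductances and ionic reversal potentials -- alter the firing rate of
    fast-spiking interneuron models.  Implements a branched-cable
    backward-Euler solver with Hodgkin-Huxley and Markov-style channel
    kinetics, Nernst reversal potentials with intracellular calcium dynamics,
    SWC morphology handling, frequency-input (f-I) curve and rheobase
    protocols, and combinatorial parameter-perturbation scans, together with
    a synthetic-cell generator so the full pipeline runs without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
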