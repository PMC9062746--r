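Package: fhnlayers
Title: Coherence Resonance in Two-Layered Excitatory-Inhibitory FitzHugh-Nagumo Networks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of noise-induced coherence in two-layered
    networks of excitatory and inhibitory FitzHugh-Nagumo neurons. One layer
    holds excitatory and the other inhibitory neurons; within-layer coupling is
    an undirected random geometric graph in the unit square, and between-layer
    coupling is a directed vertex-fitness network whose threshold is calibrated
    to a target mean interlayer degree. The package provides a compiled
    stochastic integrator for the coupled dynamics, correlation-time based
    coherence measures built on the normalized autocorrelation function,
    synthetic validation signals with known autocorrelation structure, and
    realization-averaged parameter sweeps that locate the coherence-resonance
    optimum and quantify how excitation-inhibition balance and interlayer
    architecture shape spiking regularity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
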