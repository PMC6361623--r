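Package: blgamma
Title: Biophysical Simulation and Analysis of Gamma Oscillations in the
    Basolateral Amygdala Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based network model of the rat basolateral amygdala
    (BL): multicompartment Hodgkin-Huxley principal neurons and fast-spiking
    interneurons, AMPA/NMDA/GABA-A synapses with short-term presynaptic
    plasticity, gap junctions, distance-dependent stochastic wiring in a
    cuboid volume, naturalistic afferent drive and Ornstein-Uhlenbeck
    background conductances. Extracellular potentials are computed from
    per-compartment transmembrane currents with the line-source
    approximation. Includes the accompanying analysis toolbox: Morlet and
    Welch spectra, gamma-burst detection on single electrodes and as
    four-dimensional spatiotemporal events on electrode grids, spike-field
    entrainment (resultant vector, pairwise phase consistency),
    autocorrelation-corrected spike coherence, and in-silico experiment
    protocols (connection ablations, two-ensemble competition).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
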