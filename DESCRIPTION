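Package: neurores
Title: Neuronal Resonance Across Levels of Organization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for studying how neuronal
    resonance arises and propagates across levels of organization: membrane
    potential fluctuations, single-neuron spiking, short-term synaptic
    dynamics, and small networks. Provides conductance-based and
    integrate-and-fire cell models (persistent sodium plus h-current,
    leaky integrate-and-fire, a spike-triggered calcium variant, a
    4D pyramidal cell, and a Wang-Buzsaki interneuron with an M-like
    current), a fixed-step second-order Runge-Kutta integrator with
    threshold-clamp-reset spiking, sinusoid/chirp stimulus and synthetic
    spike-train generators, network presets (excitatory-inhibitory motifs,
    a diverging-converging feedforward network, and feedforward
    inhibition), and resonance metrics: impedance profiles, cycle-averaged
    firing rates, frequency-phase fingerprints, and spike-input spectral
    coherence.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
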