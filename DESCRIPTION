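Package: gammanet
Title: Spiking Cortical Network Model of Gamma Oscillations Under NMDA
    Receptor Block
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for a sparsely connected
    cortical network of adaptive exponential integrate-and-fire neurons
    (regular-spiking excitatory and fast-spiking inhibitory cells) with
    conductance-based AMPA, GABA-A and voltage-dependent NMDA synapses.
    Implements the magnesium-block NMDA conductance, Poissonian external
    drive with Gaussian-envelope stimuli, a kernel-based local field
    potential proxy, Welch spectral analysis with gamma/asynchronous state
    classification, synaptic charge ratios, and a paired-simulation
    responsiveness protocol used to study how partial NMDA receptor block
    (as produced by dissociative anaesthetics such as ketamine) reshapes
    gamma rhythms and network responsiveness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
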