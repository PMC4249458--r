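Package: purkinet
Title: Spiking Network Model of Cerebellar Purkinje Cells and Molecular
    Layer Interneurons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Conductance-based leaky integrate-and-fire simulation of the
    cerebellar molecular-layer microcircuit: spontaneously active Purkinje
    cells and molecular layer interneurons wired along a one-dimensional
    parasagittal strip with probabilistic, anatomically constrained
    inhibitory connectivity. Provides the stochastic single-neuron model
    (gamma-distributed endogenous depolarizing current, spike-triggered
    after-hyperpolarization conductance), a seeded network generator with
    convergence/divergence targets, a fixed-step Euler simulation engine,
    spike-train statistics (firing rates, inter-spike-interval coefficient
    of variation, histograms, autocorrelograms, rank correlations), and
    scripted in-silico experiments: isolated-neuron firing, intact-network
    irregular firing, feedforward-inhibition interval prolongation, synapse
    pruning, spontaneous-drive calibration, and robustness analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
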