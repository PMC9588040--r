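Package: stcnet
Title: Spiking Network Simulation of Neuromodulator-Dependent Synaptic
    Tagging and Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates recurrent networks of leaky integrate-and-fire
    neurons with Ornstein-Uhlenbeck background and stimulus drive,
    calcium-based early-phase synaptic plasticity, and synaptic tagging
    and capture with a neuromodulator-dependent protein synthesis
    threshold. Provides learning/recall protocols with an analytic
    fast-forward of the consolidation phase, and analysis tools for
    pattern completion, firing-rate mutual information, PCA
    dimensionality, spike-time stability with shuffled controls, and
    ridge-regression readout of temporal sequences.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
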