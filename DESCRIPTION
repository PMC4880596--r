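Package: mspnet
Title: Self-Organizing Spiking Networks via Homeostatic Structural Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates leaky integrate-and-fire networks in which the
    connectivity is not prescribed but grows: each neuron tracks its own
    activity through an exponentially decaying calcium trace, grows or
    retracts axonal and dendritic synaptic elements according to
    calcium-dependent homeostatic growth curves, and a global connectivity
    manager pairs vacant elements at random to form synapses and breaks
    synapses whose elements are deleted. Networks wire themselves toward
    per-population activity setpoints. Includes builders for a simple
    two-population network and an eight-population cortical-microcircuit
    layout, recorders for spikes, calcium and connectivity, and tools to
    compare generated connectivity against a reference map.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
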