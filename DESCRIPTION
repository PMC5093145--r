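Package: snnsort
Title: Unsupervised Spike Sorting with a Memristive Spiking Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of a two-layer leaky integrate-and-fire spiking neural
    network that performs unsupervised spike sorting of single-channel
    extracellular recordings. A bank of narrow Butterworth band-pass filters
    encodes the continuous voltage trace into rectified frequency-channel
    drives; 32 input neurons project through compound synapses, each built
    from parallel binary resistive-memory (OxRAM) devices with stochastic
    programming, onto 5 output neurons under winner-take-all lateral
    inhibition. Synaptic weights are learned online by a simplified
    probabilistic spike-timing-dependent plasticity rule. The package includes
    a synthetic extracellular-recording generator with ground truth,
    recognition-rate evaluation, per-event energy and endurance accounting for
    the memory devices, and a small genetic-algorithm parameter tuner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
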