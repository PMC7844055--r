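Package: snndecoder
Title: Spiking Neural Network Decoding of Continuous Motor Signals from
    Multichannel Brain Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for decoding continuous target signals (muscle-activity and
    kinematics-like traces) from multichannel brain signals (EEG-like time
    series) with a brain-inspired spiking neural network. Implements a
    threshold-based spike codec, a three-dimensional small-world spiking
    reservoir of leaky integrate-and-fire neurons trained with a fire-triggered
    variant of spike-timing-dependent plasticity, and an evolving output layer
    of spike pattern association neuron (SPAN) populations trained with a
    spike-domain delta rule. Includes a seeded generator of event-locked
    synthetic sessions, lagged cross-correlation evaluation, pseudo-online
    streaming prediction, learning-curve and region-connectivity summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
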