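Package: aosim
Title: Simulation of a Receptor-Based Artificial Olfactory System with
    Organic Synaptic Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the computational chain of a bioelectronic nose built from
    human olfactory receptor (hOR) sensor channels wired to organic synaptic
    devices: saturating-exponential long-term potentiation/depression (LTP/LTD)
    conductance curves and their nonlinearity fitting, excitatory postsynaptic
    current (EPSC) relaxation and paired-pulse facilitation, a synthetic-data
    generator for odorant- and channel-specific conductance responses of
    short-chain fatty acids and their equimolar mixtures, conversion of
    three-channel responses into 9 x 3 binary combinatorial odor patterns, a
    device-nonlinearity-constrained two-layer perceptron trained by
    pulse-quantized conductance updates, and sensor statistics (fluorescence
    quenching normalization, principal component analysis of response patterns,
    3 sigma/S detection limits, mixture combinatorics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
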