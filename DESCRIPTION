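Package: meastim
Title: Single-Neuron Electrical Stimulation on High-Density Microelectrode Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to design and analyse single-neuron electrical-stimulation
    experiments on CMOS high-density microelectrode arrays (HD-MEAs).
    Implements charge-balanced stimulation-waveform construction and charge
    accounting in current and voltage mode, an electrode-electrolyte
    equivalent-circuit model with transient fitting for charge-transfer
    resistance and double-layer capacitance, seeded synthetic multi-electrode
    recordings with extracellular action-potential footprints, stimulation
    artifacts and stochastic evoked responses, threshold-based spike and
    evoked-response detection with activation-curve estimation, and a
    finite-difference quasi-static field solver for multi-electrode
    stimulation configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    rhdf5,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
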