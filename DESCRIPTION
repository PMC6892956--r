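Package: nvfusion
Title: Bimodal EEG-fNIRS Resting-State Connectivity and Neurovascular Fusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resting-state analysis of prefrontal cortex function from
    simultaneous EEG and functional near-infrared spectroscopy (fNIRS)
    recordings. Implements synchronization-likelihood (SL) electrode
    networks with automatic embedding-parameter derivation, modified
    Beer-Lambert conversion of dual-wavelength optical density to
    oxy-/deoxyhemoglobin concentration changes, Pearson/Fisher-z
    hemodynamic connectivity with top-fraction network thresholding and
    degree strength, permutation and cluster-based permutation group
    inference over sensor-pair networks, and multimodal source power
    comodulation (mSPoC) spatial-filter fusion of band power with
    hemodynamics. A synthetic-cohort generator plants known neurovascular
    coupling so that every stage is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
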