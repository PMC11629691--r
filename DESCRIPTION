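Package: ssvepcollab
Title: Collaborative SSVEP Brain-Computer Interface Simulation and Analysis
Version: 0.1.0
Authors@R:
    person("ssvepcollab", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hardware-free toolkit for multi-user steady-state visually
    evoked potential (SSVEP) brain-computer interface studies. Generates
    synthetic multi-participant occipital SSVEP EEG with 1/f background
    noise and a tunable inter-brain coupling component; implements the
    standard frequency-recognition pipeline (resampling, 4-45 Hz zero-phase
    band-pass, 1-s epoching, Welch power spectral density, occipital
    band-power argmax decoding) for both individual and collaborative
    decoding; quantifies inter-brain coupling by Fisher-Z aggregated
    channel-wise band-power correlations with a normal-theory significance
    test; and provides a message-based multi-user session server with
    closed-loop feedback to simulated clients, EDF+ archival, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
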