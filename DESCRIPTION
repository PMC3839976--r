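Package: micf
Title: Motor-Imagery Command-Following Analysis for Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for detecting motor-imagery
    command-following in multichannel EEG, as used in brain-computer
    interfacing and disorders-of-consciousness research. Provides a
    synthetic cohort generator with mu-rhythm event-related
    desynchronization and imagery-locked coherence coupling; zero-phase
    Butterworth filtering, epoching and threshold-based artifact
    rejection; a battery of 20 spectral, connectivity, complexity and
    entropy features; leave-one-out cross-validated classification
    (diagonal quadratic discriminant analysis, k-nearest neighbour,
    linear support vector machine); proportional-chance significance
    statistics with Benjamini-Hochberg false-discovery-rate control; and
    pooled-coherence condition-difference maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    signal,
    e1071,
    nortest,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
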