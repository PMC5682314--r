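Package: mmgesture
Title: Finger-Gesture Recognition from Mechanomyogram Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A processing and evaluation pipeline for recognising individual
    finger taps from two-channel mechanomyogram (MMG) accelerometer recordings.
    Provides band-pass preprocessing, two automatic tapping-event-detection
    algorithms (sliding RMS envelope and difference-template convolution),
    wavelet-packet decomposition with singular-value feature compression,
    within/between-class distance feature ranking, naive Bayes, k-nearest
    neighbour and polynomial-kernel support vector machine classifiers with
    stratified cross-validation, and a synthetic MMG recording generator with
    exact ground-truth event annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
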