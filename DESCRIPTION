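Package: hypnomem
Title: Memory-Augmented Feedforward Sleep Staging from Single-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lightweight hybrid sleep-staging framework for single-channel
    (frontopolar) EEG. Extracts a fixed 37-feature vector per scoring epoch
    (time-domain moments, Higuchi fractal dimension, Hjorth parameters,
    spectral band-power ratios, spectral shape descriptors, and Daubechies-4
    wavelet sub-band features), augments it with a first-order Markov
    transition-vector memory feature, and classifies stages (W, N1, N2, N3,
    REM) with paired feedforward neural networks (with and without memory)
    fused by a confidence threshold with a not-classified fallback. Includes
    hypnogram autocovariance and autocorrelation-time analysis, a synthetic
    polysomnography generator for fully reproducible experiments, and
    leave-one-subject-out evaluation with permutation feature importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
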