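Package: emdeeg
Title: Emotion Recognition from EEG in the Empirical Mode Decomposition Domain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes EEG epochs into intrinsic mode functions (IMFs) by
    empirical mode decomposition (EMD), extracts three per-IMF features
    (mean absolute first difference of the time series, mean absolute first
    difference of the unwrapped Hilbert phase, and log normalized energy),
    ranks electrodes by two-class Fisher distance, and classifies binary
    valence/arousal labels with leave-one-trial-out support vector machine
    evaluation. Includes classical comparison baselines (box-counting
    fractal dimension, sample entropy, db4 wavelet differential entropy of
    the Beta and Gamma bands), readers for the DEAP preprocessed per-subject
    array layout, and a seeded synthetic generator of DEAP-shaped two-class
    datasets so the whole pipeline is testable without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
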