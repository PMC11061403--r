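Package: nftda
Title: Neural-Field-Theory Data Augmentation for Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Corticothalamic neural-field modelling for motor-imagery
    brain-computer interfaces. Provides the analytic EEG power spectrum of the
    linearized corticothalamic model, a seeded time-domain and
    spectral-synthesis simulator of cortical source activity, Markov chain
    Monte Carlo fitting of model gains to experimental spectra, a common
    spatial patterns (CSP) classification pipeline with total-power and
    Higuchi-fractal-dimension features, model-based training-data augmentation
    of CSP source epochs with optional physiological parameter jittering, a
    feature-space noise-augmentation baseline, and an inverse cross-validation
    protocol for quantifying the classification-accuracy benefit of
    augmentation on small training sets. Includes a synthetic-cohort generator
    so the full pipeline is testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    MASS,
    signal,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    readr,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    broom,
    optparse
Config/testthat/edition: 3
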