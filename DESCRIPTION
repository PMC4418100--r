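Package: movesync
Title: Time-Scale Synchrony and Spectral Colour of Animal Movement
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Spectral analysis of daily displacement series from
    radiotelemetry studies of free-ranging animals.  Provides a
    skewness-minimising power transform for displacement panels, Fourier
    decomposition into phases and periodogram ordinates, a hierarchical
    Bayesian wrapped-Cauchy model that detects the time scale above which
    movement is synchronous across individuals (DIC cutoff scan), and
    hierarchical estimation of 1/f-noise colour under the Whittle
    approximation, together with a ground-truth synthetic data generator
    for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
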