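Package: sdngc
Title: Granger Causality with Signal-Dependent Noise for Multi-Trial Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting directed (Granger) influence between
    multi-trial time series whose noise variance depends on the signal,
    as is the case for fMRI BOLD recordings driven by near-Poisson
    neuronal firing.  Implements the AR-BEKK process (an autoregression
    whose conditional covariance is a quadratic function of the lagged
    process), its stability theory and seeded simulation, constrained
    maximum-likelihood estimation, likelihood-ratio tests for causality
    in mean and variance, a classical vector-autoregressive baseline,
    a two-sided test for the difference of causalities in opposite
    directions with a modified-Bessel-function null, projection-based
    diagnostics for signal-dependent noise, a Poisson-spiking balloon
    model BOLD simulator, wavelet denoising and trial pooling, and
    seeded synthetic benchmark studies (ROC comparison and a four-region
    two-condition panel generator).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
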