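Package: spikecoder
Title: Spike-Train Decoding Precision, Reliability Timescales, and
    Synaptic Transmission Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing the temporal structure of spike trains
    recorded (or simulated) under repeated presentations of a filtered
    white-noise stimulus. Implements cross-validated stimulus
    reconstruction with spike-triggered-average and Wiener-type filter
    models, interval-jitter estimation of spike-timing precision,
    Gaussian-kernel reliability profiles and rate/temporal coder
    classification, cross-correlogram deconvolution for monosynaptic
    spike-transmission gain, and labelled-line / summed-population /
    coincidence-detection models of synaptic transmission. A
    non-homogeneous Poisson point-process simulator generates synthetic
    units with controlled signal and noise jitter for validating every
    estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
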