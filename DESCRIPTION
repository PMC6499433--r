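Package: v1sysid
Title: System Identification of Primary Visual Cortex Encoding Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits and compares four families of encoding models for primary
    visual cortex (V1) responses to natural images: a regularized
    linear-nonlinear-Poisson (LNP) model, a generalized linear model on a
    quadrature-pair Gabor filter bank (GFB), a data-driven convolutional
    network with a factorized readout and learned output nonlinearity, and a
    GLM readout on features of a fixed hierarchical convolutional network.
    Includes the stimulus preprocessing pipeline (contrast matching, cosine
    fade mask, crop/resample/z-score), Poisson mini-batch training with early
    stopping and per-neuron hyperparameter search, the explainable-variance
    noise ceiling and fraction-of-explainable-variance-explained (FEV)
    evaluation, in-silico tuning characterization (orientation tuning width,
    phase tuning, simple-complex linearity index), and a synthetic V1
    population generator with Poisson trial-to-trial variability for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
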