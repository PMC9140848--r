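Package: phitau
Title: Integrated Information Across Timescales in Continuous Neural Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to locate the temporal scale at which integrated
    information (Phi, IIT 3.0) peaks in continuous multichannel recordings
    and in matched generative models. Simulates nonlinear and non-Markovian
    threshold-gated autoregressive systems of two or three channels, builds
    timescale-parameterised transition probability matrices from
    median-binarised signals by the skipping or downsampling (bin-averaging
    over all offsets) method, computes system-level integrated information
    for binary systems of up to three nodes with an exact earth mover's
    distance engine, and analyses Phi-versus-timescale curves with quadratic
    mixed-effects fits, likelihood-ratio tests and turning-point detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    lme4,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
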