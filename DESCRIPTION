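Package: placecode
Title: Interval Algebra and Spiking-Network Models for Auditory Place Coding
Version: 0.1.0
Authors@R:
    person("Placecode", "Developers", email = "placecode@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling a pure place code on the auditory tonotopic
    axis. Pure tones are represented as half-open "synaptic intervals" of
    contiguous cells whose location encodes frequency and whose length encodes
    sound pressure. The package implements the interval set algebra (addition
    as union, multiplication by an inhibitory interval as set minus), the
    bijective mapping between a discretized acoustic space and intervals,
    coding-capacity relations for flexible versus columnar architectures,
    closed-form prediction curves for combined excitatory/inhibitory inputs,
    a critical-band model of loudness summation, and a two-dimensional
    spiking network of adaptive exponential integrate-and-fire neurons with
    feedforward inhibition used to validate the algebraic predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
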