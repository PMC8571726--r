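Package: nzero
Title: Emergent Numerosity and Empty-Set Coding in Hierarchical
    Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study how visual numerosity - including the empty
    set (numerosity zero) - is represented by units of a hierarchical
    convolutional neural network. Provides the network model (with
    lateral-inhibition normalization and multiplicative response noise),
    a controlled dot-display stimulus generator with non-numerical-cue
    control sets, a two-way ANOVA screen for numerosity-selective units,
    tuning-curve characterization (distance and size effects, Gaussian
    fits on linear versus logarithmic number axes), behavioral decoding
    with support-vector classifiers (same/different matching, multi-class
    categorization), unit-silencing ablations, and an end-to-end
    experiment pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    e1071,
    minpack.lm,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
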