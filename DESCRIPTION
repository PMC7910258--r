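Package: sarvop
Title: Virtual Observation Point Compression of Local SAR Matrices for
    Parallel-Transmit MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compresses large sets of 10 g-averaged specific absorption rate
    (SAR) matrices of multi-channel MRI transmit arrays into small sets of
    virtual observation points (VOPs) using a greedy matrix-dominance
    algorithm with interchangeable overestimation terms. Four strategies are
    provided: a global-SAR overestimation matrix, a constant (diagonal)
    overestimation matrix, a local-SAR-approximating overestimation matrix
    built from an eigenvector-rescaled pre-compression, and a two-level
    "Double VOP" scheme in which a small pre-calculated VOP set supplies a
    SAR-tracking overestimation term. The two latter strategies control the
    maximum relative (rather than absolute) overestimation. Includes a
    synthetic multi-channel SAR-field generator, a random-excitation
    evaluation harness that certifies the no-underestimation guarantee, an
    HDF5 container format, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    optparse,
    rhdf5,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
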