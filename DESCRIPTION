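Package: mnflow
Title: Automated Scoring of the Cytokinesis-Block Micronucleus Assay from
    Imaging Flow Cytometry Data
Version: 0.1.0
Authors@R:
    person("mnflow", "developers", email = "mnflow@example.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit for automated scoring of the in vitro
    cytokinesis-block micronucleus (CBMN) assay from imaging flow
    cytometry single-cell images. Provides a seeded synthetic image
    generator for mono- to tetranucleated cells with and without
    micronuclei, multipage 16-bit TIFF input/output with feature-based
    single-cell gating, a nine-class Inception-style convolutional
    neural network classifier trained from scratch on the CPU,
    confusion-matrix cross-validation metrics, a Dunnett/Dunn
    dose-response significance framework on binucleated-cell
    micronucleus frequencies, and covariate benchmark-dose (BMD)
    estimation with exponential and Hill model families and
    profile-likelihood confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
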