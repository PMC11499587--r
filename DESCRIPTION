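Package: fieldplotr
Title: Plot-Grid Segmentation and Panicle Phenotyping for UAV Field Mosaics
Version: 0.1.0
Authors@R:
    person("fieldplotr", "developers", email = "fieldplotr@example.org",
           role = c("aut", "cre"))
Description: A detector-pluggable toolkit for high-throughput plot-level
    phenotyping of rice breeding trials from UAV orthomosaics. Implements
    automatic field-plot grid segmentation (tiled detection, cross-tile
    overlap merging, row/column line fitting and intersection-based grid
    completion), growth-stage binning over the full-heading-to-maturity
    interval, panicle-number-per-area quantification with a classical
    plant-sampling emulator, a four-class panicle-angle scheme, flight
    geometry arithmetic (ground sample distance, coverage rate), and a full
    instance-detection and regression/classification evaluation suite
    (IoU, AP/AR, RMSE, rRMSE, R squared, accuracy, F1). Ships a synthetic
    field simulator so every stage is testable without field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
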