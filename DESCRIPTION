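Package: topomacro
Title: Micro-Topography Screening of Macrophage Attachment and Polarization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for high-content screening of
    macrophage responses to micro-topographies. Generates in-silico topography
    libraries (circle/triangle/rectangle primitives composed into periodic
    feature blocks on a 66 x 66 chip with diagonal duplicates and flat
    controls), rasterizes designs and extracts surface descriptors including an
    iterative maximum-inscribed-circle spacing measure, quantifies cell
    attachment and per-cell M1/M2 marker intensities from multi-channel
    fluorescence frames, aggregates and filters screen tables (flat
    normalization, signal-to-noise exclusion, k-means and hierarchical
    phenotype clustering), and fits tree-ensemble regressions with
    Shapley-value feature attribution to link surface descriptors to the
    composite attachment-polarization response. A synthetic-screen generator
    with planted structure-function rules makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    EBImage,
    png,
    xgboost,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
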