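Package: cellcircuit
Title: Cell-Cell Interaction Network Motifs and Fibroblast-Macrophage
    Circuit Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for decomposing a cell-type interaction network of the
    tumor microenvironment into enriched circuit motifs, and for modeling
    the two-cell fibroblast-macrophage growth circuit. Builds weighted
    directed cell networks from interaction-strength matrices, enumerates
    and scores two- to four-node circuit patterns against degree-preserving
    randomized networks, simulates and analyzes a two-population growth
    model (phase portraits, fixed points, basins of attraction, the
    autocrine collapse threshold), fits circuit parameters to paired
    day-3/day-7 co-culture cell counts by bounded nonlinear least squares
    with bootstrap uncertainty and between-condition contrasts, and
    generates synthetic interaction networks and count datasets for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
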