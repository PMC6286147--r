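Package: polarsim
Title: Polarized-Cell Particle Simulations of Morphogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of tissue morphogenesis in which cells are
    point particles interacting through a pair potential whose attraction is
    modulated by apical-basal polarity and planar cell polarity. Neighborhoods
    follow a line-of-sight Voronoi rule, dynamics are overdamped Langevin
    integrated with the Euler method, and cells may divide on an exponential
    growth schedule. Includes generators for the standard initial conditions
    (bulk aggregates, hollow spheres, polarity boundary fields), quantification
    metrics (energy per cell, fold counting via local minima, tube semi-axes,
    nested-shell counting), and scenario presets for lumen formation, boundary-
    condition morphologies, organoid folding by growth or pressure, PCP-driven
    tubulogenesis, and gastrulation-like invagination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    igraph,
    generics,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
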