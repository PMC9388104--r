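Package: minscale
Title: Multiscale Analysis of Mass-Conserving Bulk-Surface Reaction-Diffusion Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for bridging scales in mass-conserving bulk-surface
    reaction-diffusion systems, built around the Min protein skeleton model.
    Computes laterally homogeneous steady states of membrane-bulk slices,
    exact bulk-surface dispersion relations with fastest-growing mode and
    band-edge extraction, regional (space- and time-resolved) dispersion
    relations with a commensurability-based pattern-type classifier, a
    closed one-dimensional reduced dynamics for large-scale mass
    redistribution in wedge geometries, a two-dimensional nonlinear slice
    simulator for validation, and the Aranson-Tsimring conserved-density
    model as a second worked instance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
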