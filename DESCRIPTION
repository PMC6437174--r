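Package: vasculr
Title: Whole-Tumor Microvascular Network Hemodynamics, Oxygen Transport
    and Heterogeneity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-free modeling toolkit for tumor microvascular networks
    represented as geometric graphs. Solves steady-state blood flow with the
    generalized one-dimensional Poiseuille law and empirical microvascular
    rheology (Fahraeus, Fahraeus-Lindqvist and plasma-skimming effects),
    computes intravascular oxygen transport with Hill hemoglobin saturation,
    derives voxel-grid morphometry maps (distance to nearest vessel, vascular
    length and surface-area density), classifies vessels into functional
    niches, and quantifies ensemble heterogeneity with coefficients of
    variation, correlation matrices and UPGMA clustering. Ships deterministic
    synthetic-network generators so every solver is testable without imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
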