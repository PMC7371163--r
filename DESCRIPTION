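Package: memlens
Title: Protein-Lipid Contact Analysis for Membrane Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses protein-lipid interactions in molecular dynamics
    trajectories of peripheral membrane proteins at asymmetric bilayers.
    Detects protein-lipid heavy-atom contacts under the minimum-image
    convention with a cell-list neighbor search, computes per-residue
    contact statistics with block-averaged standard errors, binding
    lifetimes and lipid partner counts, classifies PIP2 contacts by
    phosphate group and protonation state, and builds undirected
    bipartite residue-lipid interaction networks with cluster
    extraction and GraphML/SIF export. A synthetic-data module
    generates bilayer compositions and toy trajectories with planted,
    ground-truth contacts so every analysis stage is testable without
    large trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
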