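Package: pdgrid
Title: Grid-Based Spatial Phylogenetics of Occurrence Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for continental-scale spatial phylogenetics from point
    occurrence records and a rooted phylogeny. Cleans and aggregates records
    into an equal-area square grid, computes per-cell taxon richness, Margalef
    richness, sampling redundancy, Faith's phylogenetic diversity (as a
    proportion of total tree length) and relative phylogenetic diversity,
    flags cells whose phylogenetic diversity is significantly high or low
    under a fixed-margin (row- and column-sum preserving) randomization null,
    and relates each diversity metric to environmental variables with
    generalized linear models, Moran's I residual diagnostics and a
    maximum-likelihood spatial error regression. Includes a synthetic-data
    generator (pure-birth trees, gradient environments, phylogenetically
    structured community assembly) for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
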