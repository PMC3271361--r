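Package: binasr
Title: Ancestral State Reconstruction of Binary Traits over Phylogenetic Tree Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs the evolutionary history of a binary morphological
    character (such as unicellular versus multicellular growth in
    cyanobacteria) over single trees and posterior samples of trees.
    Provides generalized Fitch/Sankoff parsimony with most-parsimonious
    reconstruction (MPR) state sets and directional transition counts,
    maximum-likelihood inference under the one-rate (Mk1) and two-rate
    (AsymmMk) continuous-time Markov models with equilibrium root
    frequencies, marginal ancestral reconstruction, reversible-jump MCMC
    with exponential rate priors under a uniform hyperprior, stepping-stone
    marginal-likelihood estimation for Bayes factors, node matching and
    pie-chart-style aggregation across tree samples, a tip-shuffling
    permutation test of phylogenetic conservatism, and a synthetic-data
    generator emulating the statistical structure of 16S-based
    cyanobacterial datasets.
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
    phangorn,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr
LinkingTo: Rcpp
Suggests:
    Matrix,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
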