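Package: cdexplain
Title: Explaining Stochastic Community Detection with Interpretable Graph Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A model-agnostic pipeline for explaining the behaviour of
    stochastic community-finding algorithms (Infomap, Louvain, label
    propagation) on undirected graphs. From many seeded runs of an
    algorithm the package builds a coassociation matrix, derives
    "easy/hard to cluster" node labels from per-node entropy and
    "same/different community" node-pair labels, computes interpretable
    structural and community-dependent graph features, ranks features by
    random-forest permutation importance under repeated cross-validation,
    and compares the resulting importance distributions with a
    nonparametric multiple-comparison workflow (Shapiro-Wilk screening,
    power analysis, pairwise Wilcoxon signed-rank tests with
    Bonferroni-Holm correction). Includes an LFR-style benchmark graph
    generator and fast planted-partition fixtures for fully synthetic,
    reproducible experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    ranger,
    jsonlite,
    yaml,
    generics,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
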