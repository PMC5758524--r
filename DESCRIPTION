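Package: dmnet
Title: Two-Layer Plant-Bird Mutualism Networks and Double Mutualisms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building and analysing two-layered (pollination plus
    seed-dispersal) bipartite plant-bird mutualism networks. Detects double
    mutualisms (the same plant-bird pair linked in both layers), tests their
    excess against randomization null models (fill-preserving, checkerboard
    degree-preserving, and the Ce cell-probability model), and computes the
    architecture metrics used in island network studies: connectance under
    single- and doubled-denominator conventions, NODF nestedness with Ce-null
    significance, Newman modularity optimized by simulated annealing with a
    degree-preserving null, betweenness centrality by mutualist role, and
    quantitative species dependence and strength. Includes a seeded synthetic
    generator of coupled two-layer networks with abundance-driven degree
    heterogeneity for calibration and power analysis, edge-list and matrix
    readers and writers, Pajek and GraphML export, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
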