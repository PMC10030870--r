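Package: neulay
Title: Neural-Network Accelerated Force-Directed Graph Layouts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Force-directed layout (FDL) of undirected networks in two or three
    dimensions by gradient descent on an elastic-plus-short-range-repulsion
    energy, together with the NeuLay family of accelerated layouts that
    reparametrize node coordinates through a trainable node embedding (NodeMLP)
    or one or two graph-convolutional layers (NeuLay, NeuLay-2) and train the
    network weights on the same energy. Includes seeded benchmark graph
    generators (Erdos-Renyi, Barabasi-Albert, stochastic block model, random
    geometric graphs, cubic lattices), spectral analysis of the normalized
    adjacency operator with outlier-eigenvalue detection and top/bulk operator
    splitting, layout-quality metrics (final energy ratio, steps-to-target
    speedup, link-length distributions, community localization, geometric
    randomization null, cluster separation), a reproducible experiment harness,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    cluster
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
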