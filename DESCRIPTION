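Package: evsa
Title: Network Comparison with Eigenvector Signatures
Version: 0.1.0
Authors@R: person("EVSA", "Developers", email = "maintainer@evsa-project.org",
    role = c("aut", "cre"))
Description: Spectral signatures for pairwise comparison of undirected
    networks. A network's signature is the descending-sorted
    Perron-Frobenius eigenvector of its adjacency matrix; the Euclidean
    distance between signatures (EVSD) and its complement (EVSA) quantify
    network dissimilarity and similarity, and sorting the signatures solves
    the node-alignment problem implied by the Blondel node-similarity
    matrix in O(N log N) instead of O(N^3). Includes edge-list input and
    output, classical random-graph generators (Erdos-Renyi,
    Barabasi-Albert, 3D geometric, stickiness) with average-degree
    calibration, perturbation protocols, and drivers for control tests and
    model-matching experiments on protein-protein interaction style
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
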