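# evsa — network comparison with eigenvector signatures

`evsa` compares undirected networks — protein–protein interaction (PPI)
graphs in particular — through a spectral fingerprint cheap enough for
large-scale screening.  It is aimed at systems biologists who want to ask
"which random-graph model best explains this interactome?" or "how far has
this network drifted from its reference?" without solving a graph-matching
problem per comparison.

## The statistic

The **eigenvector signature** (EVS) of a graph *G* with adjacency matrix
*A* is the descending-sorted, unit-norm Perron–Frobenius (dominant)
eigenvector of *A*:

    s↓ = sort(u, decreasing),   A u = λ₁ u,   u ≥ 0,   ‖u‖₂ = 1.

Sorting discards the node labelling, so isomorphic graphs have identical
signatures.  Comparison is by the **eigenvector signature distance** and
its complement, the **agreement**:

    EVSD(G₁, G₂) = ‖s₁↓ − s₂↓‖₂ / √2 ∈ [0, 1],
    EVSA(G₁, G₂) = 1 − EVSD(G₁, G₂),

where √2 is the diameter of the set of non-negative unit vectors, and the
shorter signature is zero-padded when sizes differ.  The same sort also
solves a real alignment problem: the Blondel node-similarity matrix between
two undirected graphs converges to the rank-1 product u₁u₂ᵀ, and by the
rearrangement inequality the assignment problem on that matrix is solved by
pairing nodes rank-by-rank — O(N log N) instead of the Hungarian
algorithm's O(N³).  `blondel_similarity()` and `assignment_oracle()` are
included as independent oracles certifying this reduction on small graphs.

The package also ships the four reference generators used in the
control-test literature (Erdős–Rényi, Barabási–Albert, 3D geometric, and
the degree-sequence-driven stickiness model for PPI networks), calibration
to a target average degree, perturbation protocols (random edge attachment,
sub-network injection), and experiment drivers (`control_test()`,
`model_match()`, `grid_comparison()`, `jaccard_distance()`).

## Worked example

Generate a 500-node geometric random graph calibrated to average degree 10,
perturb it by attaching 50% extra random edges, and compare:

```r
library(evsa)

ref  <- generate_network(calibrate_model("GEO3D", 500, 10, seed = 1), seed = 2)
graph_stats(ref)
#> Graph: 500 nodes, 2418 edges, density 0.0193, average degree 9.672

pert <- attach_random_edges(ref, 0.5, seed = 3)

pf_vector(ref)
#> Eigenvector signature: 500 nodes, lambda = 15.582729, top values 0.24130 0.23992 0.23953 0.23261 0.22095

network_evsa(ref, pert)
#> [1] 0.6301355

align_networks(ref, pert)
#> Signature alignment: 500 pairs, objective 0.863200, EVSA 0.630136
```

The agreement of 0.63 says that violating the geometric constraints of a
spatial network with random long-range edges changes its dominant
eigenvector drastically — the same perturbation applied to an Erdős–Rényi
reference leaves EVSA around 0.94 (`control_test("ER", ...)` reproduces the
whole published perturbation table; means for ER at φ = 0.1…0.5 under test
(a) come out 0.981…0.945 here).  `model_match(query, ...)` ranks candidate
generators by mean EVSA against a query network; a stickiness-model query
built from a heavy-tailed 111-node degree sequence is correctly matched to
STICKY ahead of ER, BA and GEO3D.

A command-line front end is installed at `exec/evsa` inside the package
directory (`evsa stats`, `signature`, `compare`, `align`, `generate`,
`perturb`, `control-test`, `match`).

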