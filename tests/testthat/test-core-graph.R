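test_that("edge-list parsing relabels, deduplicates and rejects self-loops", {
  f <- withr::local_tempfile(fileext = ".edgelist")

  writeLines(c("0 1", "1 2"), f)
  g <- read_edgelist(f)
  expect_equal(g$n_nodes, 3L)
  expect_equal(n_edges(g), 2L)

  writeLines(c("a b", "b a", "a b"), f)
  g <- read_edgelist(f)
  expect_equal(g$n_nodes, 2L)
  expect_equal(n_edges(g), 1L)
  expect_equal(g$labels, c("a", "b"))

  writeLines("0 0", f)
  expect_error(read_edgelist(f), "line 1.*self-loop")

  writeLines(c("0 1", "2"), f)
  expect_error(read_edgelist(f), "line 2")

  # comments, blank lines, and a nodes: header declaring isolated nodes
  writeLines(c("# nodes: 5", "", "0 1  # an edge", "3 4"), f)
  g <- read_edgelist(f)
  expect_equal(g$n_nodes, 5L)
  expect_equal(n_edges(g), 2L)
  expect_equal(lengths(connected_components(g)), c(2L, 1L, 2L))
})

test_that("read/write round-trip is the identity on random graphs", {
  f <- withr::local_tempfile(fileext = ".edgelist")
  for (seed in 1:20) {
    n <- 2L + (seed %% 7L)
    g <- gen_er(n, 0.4, seed)
    write_edgelist(g, f)
    g2 <- read_edgelist(f)
    expect_equal(g2$n_nodes, g$n_nodes)
    expect_identical(edge_set(g2), edge_set(g))
  }
  # degenerate: no edges at all
  g <- evsa_graph(matrix(integer(0), ncol = 2), n_nodes = 4L)
  write_edgelist(g, f)
  g2 <- read_edgelist(f)
  expect_equal(g2$n_nodes, 4L)
  expect_equal(n_edges(g2), 0L)
})

test_that("graph statistics follow 2M/(N(N-1)) and 2M/N exactly", {
  s <- graph_stats(k2())
  expect_equal(s$density, 1)
  expect_equal(s$avg_degree, 1)

  g <- gen_er(60, 0.2, 5)
  s <- graph_stats(g)
  m <- n_edges(g)
  expect_equal(s$density, 2 * m / (60 * 59))
  expect_equal(s$avg_degree, 2 * m / 60)
  expect_equal(sum(s$degree_sequence), 2L * m)
})

test_that("printed statistics reproduce the herpesvirus PPI summary table", {
  # (name, N, M, printed density, printed average degree)
  rows <- list(
    list("HSV", 48L, 100L, "0.0886", "4.167"),
    list("VZV", 55L, 159L, "0.1070", "5.782"),
    list("KSPV", 50L, 115L, "0.0938", "4.600"),
    list("EBV", 60L, 208L, "0.1175", "6.933"),
    list("mCMV", 111L, 393L, "0.0643", "7.081")
  )
  for (r in rows) {
    # any graph with the right (N, M): take the M lexicographically first pairs
    g <- evsa_graph(evsa:::index_to_pair(seq_len(r[[3]]), r[[2]]), n_nodes = r[[2]])
    f <- format(graph_stats(g))
    expect_equal(unname(f["density"]), r[[4]], label = r[[1]])
    expect_equal(unname(f["avg_degree"]), r[[5]], label = r[[1]])
  }
})

test_that("statistics are invariant under node relabeling", {
  g <- gen_er(30, 0.3, 11)
  for (seed in 1:5) {
    sigma <- evsa:::with_seed(seed, sample.int(30))
    s1 <- graph_stats(g)
    s2 <- graph_stats(permute_graph(g, sigma))
    expect_equal(s2$density, s1$density)
    expect_equal(s2$avg_degree, s1$avg_degree)
    expect_equal(sort(s2$degree_sequence), sort(s1$degree_sequence))
  }
})

test_that("connected components partition the node set", {
  expect_equal(connected_components(k3()), list(1:3))
  expect_equal(
    connected_components(evsa_graph(rbind(c(1, 2), c(3, 4)))),
    list(c(1L, 2L), c(3L, 4L))
  )
  g <- evsa_graph(matrix(integer(0), ncol = 2), n_nodes = 5L)
  expect_equal(connected_components(g), as.list(1:5))

  # oracle cross-check on random graphs
  for (seed in 1:10) {
    g <- gen_er(25, 0.06, seed)
    comps <- connected_components(g)
    expect_setequal(unlist(comps), 1:25)
    ig <- igraph::graph_from_edgelist(g$edges, directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, 25 - igraph::gorder(ig)))
    expect_equal(
      sort(lengths(comps), decreasing = TRUE),
      sort(as.integer(igraph::components(ig)$csize), decreasing = TRUE)
    )
  }
})

test_that("pair indexing round-trips over the full triangle", {
  for (n in c(2L, 3L, 7L, 31L)) {
    np <- n * (n - 1L) / 2L
    pairs <- evsa:::index_to_pair(seq_len(np), n)
    expect_true(all(pairs[, 1L] < pairs[, 2L]))
    expect_equal(nrow(unique(pairs)), np)
    expect_equal(evsa:::pair_to_index(pairs[, 1L], pairs[, 2L], n), as.numeric(seq_len(np)))
  }
})
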