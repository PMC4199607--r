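# Small named graphs and random-graph helpers used across the suite.

g_edges <- function(...) {
  evsa_graph(do.call(rbind, list(...)))
}

k2 <- function() g_edges(c(1, 2))
k3 <- function() g_edges(c(1, 2), c(2, 3), c(1, 3))
p3 <- function() g_edges(c(1, 2), c(2, 3))  # node 2 is the centre
star4 <- function() g_edges(c(1, 2), c(1, 3), c(1, 4))

# ER draw conditioned on connectedness (redraw until connected)
rand_connected <- function(n, p, seed) {
  for (k in 0:200) {
    g <- gen_er(n, p, child_seed(seed, k))
    if (length(connected_components(g)) == 1L) return(g)
  }
  stop("no connected draw in 200 attempts")
}

# connected and non-bipartite
rand_conn_nonbip <- function(n, p, seed) {
  for (k in 0:500) {
    g <- gen_er(n, p, child_seed(seed, 1000L + k))
    if (length(connected_components(g)) == 1L && !evsa:::is_bipartite(g)) {
      return(g)
    }
  }
  stop("no connected non-bipartite draw in 500 attempts")
}

# relabel nodes by a permutation sigma: new id of node v is sigma[v]
permute_graph <- function(g, sigma) {
  e <- g$edges
  e[] <- sigma[e]
  evsa_graph(e, n_nodes = g$n_nodes)
}

# dominant-eigenpair oracle via dense eigendecomposition
eigen_oracle <- function(g) {
  ev <- eigen(adjacency_matrix(g), symmetric = TRUE)
  v <- abs(ev$vectors[, 1L])
  list(values = sort(v / sqrt(sum(v^2)), decreasing = TRUE),
       lambda = ev$values[1L])
}

# all permutations of 1..n (for tiny assignment enumeration)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos)
    }
  }
  out
}

edge_set <- function(g) {
  if (nrow(g$edges) == 0L) return(character(0))
  sort(paste(g$edges[, 1L], g$edges[, 2L]))
}
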