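# Perturbation protocols for the control tests: random edge attachment
# (test a) and sub-network injection (tests b-e), parameterised by the
# perturbation fraction phi.

#' Attach random extra edges
#'
#' Adds exactly `round(phi * M)` new edges drawn uniformly without
#' replacement from the currently absent node pairs; existing edges are
#' untouched.
#'
#' @param g an `evsa_graph`.
#' @param phi perturbation fraction in `[0, 1]`; the number of new edges is
#'   `round(phi * n_edges(g))`.
#' @param seed integer RNG seed.
#' @return An `evsa_graph` whose edge set is a superset of `g`'s.
#' @export
attach_random_edges <- function(g, phi, seed) {
  stopifnot(inherits(g, "evsa_graph"), phi >= 0, phi <= 1)
  n <- g$n_nodes
  m <- nrow(g$edges)
  k <- round(phi * m)
  if (k == 0) return(g)
  npairs <- n * (n - 1) / 2
  absent <- setdiff(seq_len(npairs), edge_indices(g))
  if (k > length(absent)) {
    stop(sprintf(
      "cannot attach %d edges: only %d node pairs are free", k, length(absent)
    ))
  }
  new_idx <- with_seed(seed, absent[sample.int(length(absent), k)])
  evsa_graph(
    rbind(g$edges, index_to_pair(new_idx, n)),
    n_nodes = n, labels = g$labels
  )
}

#' Replace the wiring among a random node subset by a model graph
#'
#' Selects `round(phi * N)` nodes uniformly, deletes every edge of the
#' induced subgraph on the selection (edges with at least one endpoint
#' outside are kept exactly), and unions in a graph generated on the
#' selected nodes from the requested model.  The injected graph is
#' calibrated to the deleted edge count, so the perturbation changes
#' topology rather than density: ER uses `p = deleted / (s (s - 1) / 2)`,
#' GEO3D bisects its radius to the matching average degree, BA uses
#' `m = round(deleted / s)`, and STICKY reuses the deleted subgraph's degree
#' sequence.  If the deleted subgraph is empty the calibration floor is one
#' expected edge.
#'
#' @param g an `evsa_graph`.
#' @param phi fraction of nodes selected, in `[0, 1]`; `phi = 0` returns the
#'   graph unchanged, and a positive `phi` selecting fewer than 2 nodes is
#'   an error.
#' @param model injected model: `"ER"`, `"GEO3D"`, `"BA"` or `"STICKY"`.
#' @param seed integer RNG seed.
#' @return Perturbed `evsa_graph` on the same node set.
#' @export
inject_subnetwork <- function(g, phi, model = c("ER", "GEO3D", "BA", "STICKY"),
                              seed) {
  stopifnot(inherits(g, "evsa_graph"), phi >= 0, phi <= 1)
  model <- match.arg(model)
  n <- g$n_nodes
  s <- round(phi * n)
  if (s == 0) return(g)
  if (s < 2) stop("selection of a single node has no internal wiring to replace")

  sel <- with_seed(child_seed(seed, 1L), sort(sample.int(n, s)))
  in_sel <- logical(n)
  in_sel[sel] <- TRUE
  inner <- in_sel[g$edges[, 1L]] & in_sel[g$edges[, 2L]]
  outside_edges <- g$edges[!inner, , drop = FALSE]
  deleted <- g$edges[inner, , drop = FALSE]
  m_del <- nrow(deleted)

  params <- switch(model,
    ER = {
      p <- min(1, max(m_del, 1L) / (s * (s - 1) / 2))
      structure(list(model = "ER", n = s, p = p), class = "evsa_model_params")
    },
    GEO3D = calibrate_model(
      "GEO3D", s, target_avg_degree = 2 * max(m_del, 1L) / s,
      seed = child_seed(seed, 2L)
    ),
    BA = {
      m <- min(s - 1L, max(1L, as.integer(round(m_del / s))))
      structure(list(model = "BA", n = s, m = m), class = "evsa_model_params")
    },
    STICKY = {
      d <- tabulate(match(deleted, sel), nbins = s)
      if (sum(d) == 0) d[1:2] <- 1L  # calibration floor: one expected edge
      structure(
        list(model = "STICKY", n = s, degree_sequence = d),
        class = "evsa_model_params"
      )
    }
  )
  injected <- generate_network(params, seed = child_seed(seed, 3L))
  new_edges <- injected$edges
  new_edges[] <- sel[new_edges]
  evsa_graph(
    rbind(outside_edges, new_edges),
    n_nodes = n, labels = g$labels
  )
}
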