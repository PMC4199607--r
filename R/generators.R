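# Random-graph models: Erdos-Renyi (ER), Barabasi-Albert preferential
# attachment (BA), 3D geometric (GEO3D) and the stickiness model (STICKY)
# used for protein-protein interaction networks, plus calibration of each
# model to a target average degree.

#' Erdos-Renyi random graph G(n, p)
#'
#' Each of the `n (n - 1) / 2` node pairs is linked independently with
#' probability `p`.
#'
#' @param n number of nodes (>= 2).
#' @param p edge probability in `[0, 1]`.
#' @param seed integer RNG seed; the same seed reproduces the same graph.
#' @return An [evsa_graph()].
#' @export
gen_er <- function(n, p, seed) {
  stopifnot(n >= 2, p >= 0, p <= 1)
  npairs <- n * (n - 1) / 2
  idx <- with_seed(seed, which(stats::runif(npairs) < p))
  evsa_graph(index_to_pair(idx, n), n_nodes = n)
}

#' Barabasi-Albert preferential-attachment graph
#'
#' Starts from a complete graph on `m + 1` nodes (so every arrival can
#' attach `m` distinct edges); each subsequent node attaches `m` edges to
#' distinct existing nodes chosen with probability proportional to their
#' current degree.  The resulting edge count is deterministic:
#' `m (m + 1) / 2 + m (n - m - 1)`.
#'
#' @param n number of nodes.
#' @param m edges attached per arriving node, `1 <= m < n`.
#' @param seed integer RNG seed.
#' @return An [evsa_graph()] whose degree distribution has a power-law tail.
#' @export
gen_ba <- function(n, m, seed) {
  stopifnot(m >= 1, m < n)
  with_seed(seed, {
    core <- t(utils::combn(m + 1L, 2L))
    edges_i <- core[, 1L]
    edges_j <- core[, 2L]
    # multiset of endpoints: node v appears deg(v) times
    reps <- rep(seq_len(m + 1L), each = m)
    if (n > m + 1L) {
      for (v in (m + 2L):n) {
        chosen <- integer(0)
        while (length(chosen) < m) {
          pick <- reps[sample.int(length(reps), m - length(chosen), replace = TRUE)]
          chosen <- unique(c(chosen, pick))
        }
        edges_i <- c(edges_i, chosen)
        edges_j <- c(edges_j, rep(v, m))
        reps <- c(reps, chosen, rep(v, m))
      }
    }
    evsa_graph(cbind(edges_i, edges_j), n_nodes = n)
  })
}

#' 3D geometric random graph
#'
#' Drops `n` points uniformly in the unit cube and links every pair at
#' Euclidean distance strictly below the threshold radius `r`.
#'
#' @param n number of nodes.
#' @param r threshold radius in unit-cube units, `0 < r < sqrt(3)`.
#' @param seed integer RNG seed.
#' @return An [evsa_graph()].
#' @export
gen_geo3d <- function(n, r, seed) {
  stopifnot(n >= 2, r > 0, r < sqrt(3) + 1e-12)
  with_seed(seed, {
    xyz <- matrix(stats::runif(n * 3L), ncol = 3L)
    d <- as.numeric(stats::dist(xyz))
    idx <- which(d < r)
    evsa_graph(index_to_pair(idx, n), n_nodes = n)
  })
}

#' Stickiness-model random graph
#'
#' Gives node `i` a stickiness index `theta_i = d_i / sqrt(sum(d))` from a
#' target degree sequence `d` and links each pair `(i, j)` independently
#' with probability `min(theta_i * theta_j, 1)`.  High-degree ("sticky")
#' nodes therefore interact preferentially, and the expected degree of node
#' `i` is `d_i - d_i^2 / sum(d)` (the self-pair term is excluded), so the
#' model approximately reproduces the supplied degree sequence.  Designed to
#' mimic protein-protein interaction networks from a degree sequence alone.
#'
#' @param degree_sequence non-negative integer target degrees, positive sum.
#' @param seed integer RNG seed.
#' @return An [evsa_graph()] with `length(degree_sequence)` nodes.
#' @export
gen_sticky <- function(degree_sequence, seed) {
  d <- as.numeric(degree_sequence)
  stopifnot(length(d) >= 2, all(d >= 0), sum(d) > 0)
  n <- length(d)
  theta <- d / sqrt(sum(d))
  with_seed(seed, {
    prob <- pmin(tcrossprod(theta), 1)
    pu <- prob[upper.tri(prob)]  # column-major upper triangle
    hit <- which(stats::runif(length(pu)) < pu)
    ut <- which(upper.tri(prob), arr.ind = TRUE)
    evsa_graph(ut[hit, , drop = FALSE], n_nodes = n)
  })
}

#' Calibrate a model to a target average degree
#'
#' Returns the parameter set under which the model's expected average degree
#' matches the target: ER uses the closed form `p = k / (n - 1)`; BA uses
#' `m = round(k / 2)` (edge count `~ m n`); GEO3D finds the threshold
#' radius by bisection on the empirical expected degree, estimated from
#' `pilots` pilot point sets drawn once and reused across probes (the
#' empirical degree is then monotone in `r`, so bisection terminates
#' cleanly) until the pilot mean degree is within 2% of the target; STICKY
#' is parameterised directly by a degree sequence.
#'
#' @param model one of `"ER"`, `"BA"`, `"GEO3D"`, `"STICKY"`.
#' @param n node count.
#' @param target_avg_degree desired average degree in `(0, n - 1)`
#'   (ignored for STICKY).
#' @param seed integer seed for the GEO3D pilot draws.
#' @param degree_sequence target degree sequence (STICKY only).
#' @param pilots number of pilot point sets for the GEO3D bisection.
#' @return An object of class `evsa_model_params`: list with `model`, `n`
#'   and the model parameter (`p`, `m`, `r` or `degree_sequence`), ready for
#'   [generate_network()].
#' @examples
#' calibrate_model("ER", 500, 10)$p  # 10/499
#' @export
calibrate_model <- function(model = c("ER", "BA", "GEO3D", "STICKY"),
                            n, target_avg_degree = NULL, seed = 1,
                            degree_sequence = NULL, pilots = 20) {
  model <- match.arg(model)
  out <- list(model = model, n = as.integer(n))
  if (model == "STICKY") {
    if (is.null(degree_sequence)) {
      stop("STICKY calibration requires a degree sequence")
    }
    if (length(degree_sequence) != n) {
      stop("degree sequence length must equal n")
    }
    out$degree_sequence <- degree_sequence
  } else {
    k <- target_avg_degree
    if (is.null(k) || k <= 0 || k >= n) {
      stop("target average degree must lie in (0, n - 1)")
    }
    if (model == "ER") {
      out$p <- k / (n - 1)
    } else if (model == "BA") {
      m <- max(1L, as.integer(round(k / 2)))
      if (m >= n) stop("target average degree unachievable for BA")
      out$m <- m
    } else {
      pool <- with_seed(child_seed(seed, 91L), {
        unlist(lapply(seq_len(pilots), function(i) {
          as.numeric(stats::dist(matrix(stats::runif(n * 3L), ncol = 3L)))
        }))
      })
      lo <- 0
      hi <- sqrt(3)
      r <- NA_real_
      for (it in seq_len(60L)) {
        mid <- (lo + hi) / 2
        kk <- mean(pool < mid) * (n - 1)
        if (abs(kk - k) <= 0.02 * k) {
          r <- mid
          break
        }
        if (kk < k) lo <- mid else hi <- mid
      }
      if (is.na(r)) r <- (lo + hi) / 2
      out$r <- r
    }
  }
  out$target_avg_degree <- target_avg_degree
  structure(out, class = "evsa_model_params")
}

#' Generate a graph from calibrated model parameters
#'
#' @param params an `evsa_model_params` from [calibrate_model()].
#' @param seed integer RNG seed for the draw.
#' @return An [evsa_graph()].
#' @export
generate_network <- function(params, seed) {
  stopifnot(inherits(params, "evsa_model_params"))
  switch(params$model,
    ER = gen_er(params$n, params$p, seed),
    BA = gen_ba(params$n, params$m, seed),
    GEO3D = gen_geo3d(params$n, params$r, seed),
    STICKY = gen_sticky(params$degree_sequence, seed)
  )
}
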