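# Experiment drivers: perturbation control tests, model matching of a query
# network against candidate generators, grid comparisons across sizes and
# degrees, and the histogram-overlap Jaccard divergence between score
# distributions.

perturbation_for <- function(test) {
  switch(test,
    a = function(g, phi, seed) attach_random_edges(g, phi, seed),
    b = function(g, phi, seed) inject_subnetwork(g, phi, "ER", seed),
    c = function(g, phi, seed) inject_subnetwork(g, phi, "GEO3D", seed),
    d = function(g, phi, seed) inject_subnetwork(g, phi, "BA", seed),
    e = function(g, phi, seed) inject_subnetwork(g, phi, "STICKY", seed),
    stop("unknown test id: ", test)
  )
}

#' Perturbation control test
#'
#' For each replicate, draws a fresh reference network from the requested
#' model (calibrated to `n` nodes and the target average degree), applies
#' every requested `(phi, test)` perturbation, and records the EVSA between
#' reference and perturbed network.  Test `"a"` is random edge attachment;
#' tests `"b"`-`"e"` replace the wiring of a random `phi` fraction of nodes
#' by an ER, GEO3D, BA or STICKY sub-network respectively (see
#' [inject_subnetwork()]).
#'
#' Replicate seeds are derived as `child_seed(seed, cell, replicate)`, so
#' any cell of the result table can be reproduced in isolation.
#'
#' @param reference_model `"ER"`, `"GEO3D"`, `"BA"` or `"STICKY"`.
#' @param n reference network size; default 500.
#' @param avg_degree target average degree; default 10.
#' @param phis perturbation fractions; default `seq(0, 0.5, 0.1)`.
#' @param tests subset of `c("a","b","c","d","e")`.
#' @param reps replicates per cell; default 50.
#' @param seed integer master seed.
#' @param degree_sequence reference degree sequence (STICKY reference only).
#' @return An object of class `evsa_experiment`: list with `results` (long
#'   data frame `model`, `phi`, `test`, `replicate`, `evsa`) and `summary`
#'   (per-cell `mean`, `sd`, `n`).
#' @export
control_test <- function(reference_model = c("ER", "GEO3D", "BA", "STICKY"),
                         n = 500, avg_degree = 10,
                         phis = seq(0, 0.5, by = 0.1),
                         tests = c("a", "b", "c", "d", "e"),
                         reps = 50, seed = 1, degree_sequence = NULL) {
  reference_model <- match.arg(reference_model)
  tests <- match.arg(tests, c("a", "b", "c", "d", "e"), several.ok = TRUE)
  stopifnot(all(phis >= 0), all(phis <= 1), reps >= 1)

  params <- calibrate_model(
    reference_model, n, avg_degree,
    seed = child_seed(seed, 0L), degree_sequence = degree_sequence
  )
  cells <- expand.grid(phi = phis, test = tests, stringsAsFactors = FALSE)
  funs <- lapply(cells$test, perturbation_for)

  rows <- vector("list", reps * nrow(cells))
  idx <- 0L
  for (rep in seq_len(reps)) {
    ref <- generate_network(params, seed = child_seed(seed, 1L, rep))
    sig_ref <- pf_vector(ref)
    for (ci in seq_len(nrow(cells))) {
      phi <- cells$phi[ci]
      pert <- funs[[ci]](ref, phi, child_seed(seed, 2L, ci, rep))
      score <- if (phi == 0) 1 else evsa(sig_ref, pf_vector(pert))
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        model = reference_model, phi = phi, test = cells$test[ci],
        replicate = rep, evsa = score
      )
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(
    evsa ~ model + phi + test, data = results,
    FUN = function(x) c(mean = mean(x), sd = stats::sd(x), n = length(x))
  )
  summary <- cbind(
    summary[c("model", "phi", "test")],
    as.data.frame(summary$evsa)
  )
  structure(
    list(results = results, summary = summary, seed = seed, params = params),
    class = "evsa_experiment"
  )
}

#' @export
print.evsa_experiment <- function(x, ...) {
  cat("Control-test experiment (mean EVSA per cell):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Match a query network against candidate models
#'
#' For each candidate model, generates `n_candidates` networks with the
#' query's node count, calibrated to the query's edge count (STICKY uses the
#' query's degree sequence), and scores each against the query with EVSA.
#' The model with the highest mean EVSA is the best-fitting generator for
#' the query - the experiment behind fitting PPI networks with the
#' stickiness model.
#'
#' @param query an `evsa_graph`.
#' @param models candidate model names.
#' @param n_candidates candidates per model; default 50.
#' @param seed integer master seed.
#' @return An object of class `evsa_match`: list with `scores` (long data
#'   frame `model`, `candidate`, `evsa`) and `summary` (`model`,
#'   `mean_evsa`, `sd_evsa`, `n`), ordered by decreasing mean.
#' @export
model_match <- function(query, models = c("ER", "GEO3D", "BA", "STICKY"),
                        n_candidates = 50, seed = 1) {
  stopifnot(inherits(query, "evsa_graph"), n_candidates >= 1)
  models <- match.arg(models, c("ER", "BA", "GEO3D", "STICKY"),
                      several.ok = TRUE)
  n <- query$n_nodes
  k <- 2 * nrow(query$edges) / n
  sig_q <- pf_vector(query)

  rows <- vector("list", length(models) * n_candidates)
  idx <- 0L
  for (mi in seq_along(models)) {
    params <- calibrate_model(
      models[mi], n, target_avg_degree = if (models[mi] == "STICKY") NULL else k,
      seed = child_seed(seed, 10L, mi),
      degree_sequence = if (models[mi] == "STICKY") degree_sequence(query)
    )
    for (j in seq_len(n_candidates)) {
      cand <- generate_network(params, seed = child_seed(seed, 20L, mi, j))
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        model = models[mi], candidate = j, evsa = evsa(sig_q, pf_vector(cand))
      )
    }
  }
  scores <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(scores, scores$model), function(d) {
    data.frame(
      model = d$model[1L], mean_evsa = mean(d$evsa),
      sd_evsa = stats::sd(d$evsa), n = nrow(d)
    )
  }))
  summary <- summary[order(-summary$mean_evsa), , drop = FALSE]
  rownames(summary) <- NULL
  structure(
    list(scores = scores, summary = summary, seed = seed),
    class = "evsa_match"
  )
}

#' @export
print.evsa_match <- function(x, ...) {
  cat("Model-matching experiment (mean EVSA per candidate model):\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Match/mismatch grid comparison
#'
#' For every combination of size, average degree, query model and candidate
#' model: draws one query network, then `reps` candidate networks calibrated
#' to the query's size and realised edge count, and records the EVSA of each
#' pair.  Cells where query and candidate model coincide form the "match"
#' set; the rest the "mismatch" set.  The long-format output feeds heat-map
#' summaries and [jaccard_distance()].
#'
#' @param sizes node counts.
#' @param degrees target average degrees.
#' @param models model names used both as query and candidate generators.
#' @param reps candidates per cell; default 50.
#' @param seed integer master seed.
#' @return Long data frame with columns `query_model`, `candidate_model`,
#'   `n`, `avg_degree`, `replicate`, `evsa`.
#' @export
grid_comparison <- function(sizes, degrees,
                            models = c("ER", "GEO3D", "BA"),
                            reps = 50, seed = 1) {
  stopifnot(length(sizes) > 0, length(degrees) > 0, length(models) > 0)
  rows <- list()
  cell <- 0L
  for (n in sizes) {
    for (k in degrees) {
      for (qi in seq_along(models)) {
        cell <- cell + 1L
        qparams <- calibrate_model(models[qi], n, k,
                                   seed = child_seed(seed, 30L, cell))
        query <- generate_network(qparams, seed = child_seed(seed, 31L, cell))
        kq <- 2 * nrow(query$edges) / n
        sig_q <- pf_vector(query)
        for (ci in seq_along(models)) {
          cparams <- calibrate_model(
            models[ci], n, max(kq, 1e-6),
            seed = child_seed(seed, 32L, cell, ci)
          )
          for (j in seq_len(reps)) {
            cand <- generate_network(
              cparams, seed = child_seed(seed, 33L, cell, ci, j)
            )
            rows[[length(rows) + 1L]] <- data.frame(
              query_model = models[qi], candidate_model = models[ci],
              n = n, avg_degree = k, replicate = j,
              evsa = evsa(sig_q, pf_vector(cand))
            )
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Jaccard divergence between two score distributions
#'
#' Histograms both score multisets on fixed bins over `[0, 1]` and returns
#' `1 - sum(pmin(hA, hB)) / sum(pmax(hA, hB))`: 0 for identical multisets,
#' 1 for distributions with disjoint support.  Used to quantify how well a
#' similarity score separates match-model from mismatch-model comparisons.
#'
#' @param scores_a,scores_b numeric vectors of scores in `[0, 1]`.
#' @param bin_width histogram bin width; must divide 1; default 0.01.
#' @return Divergence in `[0, 1]`.
#' @examples
#' jaccard_distance(c(0.1, 0.1, 0.4, 0.4), c(0.1, 0.4, 0.4, 0.4), 0.5)
#' @export
jaccard_distance <- function(scores_a, scores_b, bin_width = 0.01) {
  nbins <- round(1 / bin_width)
  if (abs(nbins * bin_width - 1) > 1e-9) {
    stop("`bin_width` must divide 1")
  }
  if (length(scores_a) == 0 && length(scores_b) == 0) {
    stop("both score sets are empty")
  }
  all_scores <- c(scores_a, scores_b)
  if (any(all_scores < 0 | all_scores > 1)) {
    stop("scores must lie in [0, 1]")
  }
  bin <- function(x) {
    if (length(x) == 0) return(integer(nbins))
    tabulate(pmin(floor(x / bin_width), nbins - 1) + 1L, nbins = nbins)
  }
  ha <- bin(scores_a)
  hb <- bin(scores_b)
  1 - sum(pmin(ha, hb)) / sum(pmax(ha, hb))
}
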