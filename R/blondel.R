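# Blondel node-similarity matrix and the exact assignment oracle.
#
# These two routines certify the sorting shortcut used by the signature
# scores: for undirected graphs the Blondel iteration collapses to the
# rank-1 (dyadic) product of the two Perron-Frobenius vectors, and the
# optimal assignment on that matrix equals the sorted-signature inner
# product.  Both are kept as independent reference routes and are meant for
# small problems.

#' Blondel node-similarity matrix (undirected simplification)
#'
#' Iterates `X <- B X A / ||B X A||_F` from the all-ones matrix, where `B`
#' and `A` are the adjacency matrices of `g1` and `g2`.  The Frobenius
#' normalisation is applied every step; convergence is assessed on
#' even-index iterates (the even and odd subsequences can have different
#' limits, exactly as in the directed original), and the even-iterate limit
#' is returned.  For connected non-bipartite graphs the limit is the dyadic
#' product `u1 u2'` of the two dominant eigenvectors.
#'
#' @param g1,g2 `evsa_graph` objects, each with at least one edge.
#' @param tol Frobenius-norm tolerance between consecutive even iterates;
#'   default `1e-10`.
#' @param max_iter iteration cap; default `1e4`.
#' @return `N1 x N2` non-negative matrix of unit Frobenius norm; entry
#'   `(i, j)` is the similarity of node `i` in `g1` to node `j` in `g2`.
#'   The iteration count is attached as attribute `"iterations"`.
#' @examples
#' k2 <- evsa_graph(rbind(c(1, 2)))
#' blondel_similarity(k2, k2)  # all entries 0.5
#' @export
blondel_similarity <- function(g1, g2, tol = 1e-10, max_iter = 1e4) {
  stopifnot(inherits(g1, "evsa_graph"), inherits(g2, "evsa_graph"))
  if (nrow(g1$edges) == 0L || nrow(g2$edges) == 0L) {
    stop("Blondel similarity requires graphs with at least one edge")
  }
  b <- adjacency_matrix(g1)
  a <- adjacency_matrix(g2)
  x <- matrix(1, nrow(b), nrow(a))
  x <- x / sqrt(sum(x * x))
  x_even <- x
  for (k in seq_len(max_iter)) {
    x <- b %*% x %*% a
    nrm <- sqrt(sum(x * x))
    if (nrm == 0) stop("iteration collapsed to the zero matrix")
    x <- x / nrm
    if (k %% 2L == 0L) {
      if (sqrt(sum((x - x_even)^2)) <= tol) {
        return(structure(x, iterations = k))
      }
      x_even <- x
    }
  }
  stop(sprintf(
    "Blondel iteration did not converge in %d iterations (last even-iterate change %.3e)",
    max_iter, sqrt(sum((x - x_even)^2))
  ))
}

#' Exact assignment oracle on a similarity matrix
#'
#' Solves the maximum-trace assignment problem `max_P sum_i S[i, P(i)]`
#' exactly by dynamic programming over column subsets.  Rectangular matrices
#' are allowed: every row of the smaller dimension is assigned (equivalent
#' to padding with zero rows/columns).  Complexity is `O(2^k k)` with
#' `k = min(nrow, ncol)`; the routine is a certification oracle for small
#' problems, not a production solver, and refuses `k > 16`.
#'
#' @param s non-negative numeric matrix of node-pair similarities.
#' @return List with `mapping` (data frame `node1`, `node2` of assigned
#'   pairs) and `objective` (the optimal sum).
#' @examples
#' assignment_oracle(diag(3))  # identity mapping, objective 3
#' @export
assignment_oracle <- function(s) {
  s <- as.matrix(s)
  if (any(s < 0)) stop("similarity entries must be non-negative")
  flipped <- FALSE
  if (nrow(s) > ncol(s)) {
    s <- t(s)
    flipped <- TRUE
  }
  nr <- nrow(s)
  nc <- ncol(s)
  if (nr > 16L) stop("assignment oracle is limited to min(dim) <= 16")

  # dp over subsets of columns of size <= nr; row popcount(mask) is the
  # next row to assign.  Only masks with <= nr bits matter.
  nmask <- bitwShiftL(1L, nc)
  dp <- rep(-Inf, nmask)
  choice <- integer(nmask)
  dp[1L] <- 0
  popcnt <- integer(nmask)
  for (mask in seq_len(nmask - 1L)) {
    popcnt[mask + 1L] <- popcnt[bitwShiftR(mask, 1L) + 1L] + bitwAnd(mask, 1L)
  }
  for (mask in seq_len(nmask - 1L)) {
    i <- popcnt[mask + 1L]
    if (i > nr) next
    best <- -Inf
    bestj <- 0L
    for (j in seq_len(nc)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0L) next
      cand <- dp[mask - bit + 1L] + s[i, j]
      if (cand > best) {
        best <- cand
        bestj <- j
      }
    }
    dp[mask + 1L] <- best
    choice[mask + 1L] <- bestj
  }
  full <- which(popcnt == nr) - 1L
  objective <- max(dp[full + 1L])
  mask <- full[which.max(dp[full + 1L])]

  rows <- integer(nr)
  cols <- integer(nr)
  m <- mask
  for (i in rev(seq_len(nr))) {
    j <- choice[m + 1L]
    rows[i] <- i
    cols[i] <- j
    m <- m - bitwShiftL(1L, j - 1L)
  }
  mapping <- if (flipped) {
    data.frame(node1 = cols, node2 = rows)
  } else {
    data.frame(node1 = rows, node2 = cols)
  }
  mapping <- mapping[order(mapping$node1), , drop = FALSE]
  rownames(mapping) <- NULL
  list(mapping = mapping, objective = objective)
}
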