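# Undirected simple graphs with dense 1..N node ids.
#
# Edges are stored as an M x 2 integer matrix with edges[, 1] < edges[, 2],
# lexicographically sorted and free of duplicates.  Original node labels (as
# they appeared in an edge-list file) are kept in a side vector so that files
# round-trip; generated graphs carry no labels and are written with 0-based
# integer ids, the convention used by most edge-list tooling.

#' Construct an undirected simple graph
#'
#' Builds a graph from an edge table.  Edges are canonicalised (endpoints
#' ordered, duplicates and reversed duplicates collapsed); self-loops are
#' rejected.  Node ids are dense integers `1..n_nodes`.
#'
#' @param edges two-column matrix or data frame of node ids in `1..n_nodes`,
#'   one row per edge.  May have zero rows.
#' @param n_nodes number of nodes.  Defaults to the largest id referenced in
#'   `edges`; pass explicitly to include isolated nodes.
#' @param labels optional character vector of length `n_nodes` holding the
#'   original node labels (used by [write_edgelist()]).
#' @return An object of class `evsa_graph` with elements `n_nodes`, `edges`
#'   and `labels`.
#' @examples
#' g <- evsa_graph(rbind(c(1, 2), c(2, 3), c(1, 3)))
#' graph_stats(g)
#' @export
evsa_graph <- function(edges, n_nodes = NULL, labels = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) {
    stop("`edges` must have exactly two columns")
  }
  storage.mode(edges) <- "integer"
  dimnames(edges) <- NULL
  if (anyNA(edges)) stop("`edges` contains missing or non-integer ids")
  if (nrow(edges) > 0L) {
    if (any(edges < 1L)) stop("node ids must be >= 1")
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("self-loops are not allowed in a simple graph")
    }
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, c(2L, 1L)]
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    edges <- unique(edges)
  }
  if (is.null(n_nodes)) {
    n_nodes <- if (nrow(edges) > 0L) max(edges) else 0L
  }
  n_nodes <- as.integer(n_nodes)
  if (nrow(edges) > 0L && max(edges) > n_nodes) {
    stop("edge references node id beyond `n_nodes`")
  }
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != n_nodes) {
      stop("`labels` must have length `n_nodes`")
    }
  }
  structure(
    list(n_nodes = n_nodes, edges = edges, labels = labels),
    class = "evsa_graph"
  )
}

#' @export
print.evsa_graph <- function(x, ...) {
  cat(sprintf(
    "Undirected simple graph: %d nodes, %d edges\n",
    x$n_nodes, nrow(x$edges)
  ))
  invisible(x)
}

#' Number of edges
#' @param g an `evsa_graph`.
#' @return Integer edge count M.
#' @export
n_edges <- function(g) {
  stopifnot(inherits(g, "evsa_graph"))
  nrow(g$edges)
}

#' Degree sequence
#'
#' @param g an `evsa_graph`.
#' @return Integer vector of node degrees, indexed by node id.
#' @export
degree_sequence <- function(g) {
  stopifnot(inherits(g, "evsa_graph"))
  tabulate(g$edges, nbins = g$n_nodes)
}

#' Dense adjacency matrix
#'
#' @param g an `evsa_graph`.
#' @return Symmetric 0/1 `n_nodes` x `n_nodes` numeric matrix with zero
#'   diagonal.
#' @export
adjacency_matrix <- function(g) {
  stopifnot(inherits(g, "evsa_graph"))
  n <- g$n_nodes
  a <- matrix(0, n, n)
  if (nrow(g$edges) > 0L) {
    a[g$edges] <- 1
    a[g$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  a
}

#' Read a whitespace-separated edge list
#'
#' One edge per line as two whitespace-separated node tokens.  Everything
#' after `comment_char` on a line is ignored; blank lines are skipped.  An
#' optional header comment `# nodes: N` declares the node count, which is how
#' isolated nodes survive a round trip.  Nodes are relabelled to dense ids
#' `1..N` preserving first-appearance order (or, when a `nodes:` header is
#' present and all labels are integers in `0..N-1`, by their integer value so
#' that files written by [write_edgelist()] round-trip exactly).  Duplicate
#' and reversed-duplicate edges collapse to one.
#'
#' @param path path to the edge-list file.
#' @param comment_char single character introducing comments; default `"#"`.
#' @return An [evsa_graph()].
#' @export
read_edgelist <- function(path, comment_char = "#") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  declared_n <- NA_integer_
  header <- regmatches(
    lines,
    regexpr(paste0("^\\s*", comment_char, "\\s*nodes:\\s*[0-9]+"), lines)
  )
  header <- unlist(header)
  if (length(header) > 0L) {
    declared_n <- as.integer(sub(".*nodes:\\s*", "", header[1L]))
  }

  stripped <- sub(paste0(comment_char, ".*$"), "", lines, fixed = FALSE)
  stripped <- trimws(stripped)
  keep <- which(nzchar(stripped))
  toks <- strsplit(stripped[keep], "[[:space:]]+")

  bad <- which(lengths(toks) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf(
      "line %d: expected two whitespace-separated node tokens, got %d",
      keep[bad[1L]], lengths(toks)[bad[1L]]
    ))
  }
  a <- vapply(toks, `[`, character(1L), 1L)
  b <- vapply(toks, `[`, character(1L), 2L)
  loops <- which(a == b)
  if (length(loops) > 0L) {
    stop(sprintf("line %d: self-loop on node '%s'", keep[loops[1L]], a[loops[1L]]))
  }

  if (length(a) == 0L) {
    n <- if (is.na(declared_n)) 0L else declared_n
    return(evsa_graph(matrix(integer(0), ncol = 2L), n_nodes = n))
  }

  # interleave endpoints so first-appearance order scans lines left to right
  seen <- unique(as.vector(rbind(a, b)))
  int_ok <- !is.na(declared_n) && all(grepl("^[0-9]+$", seen))
  if (int_ok && max(as.integer(seen)) <= declared_n - 1L) {
    n <- declared_n
    labels <- as.character(0:(n - 1L))
    ids_a <- as.integer(a) + 1L
    ids_b <- as.integer(b) + 1L
  } else {
    n <- length(seen)
    if (!is.na(declared_n)) {
      if (declared_n < n) {
        stop("declared node count is smaller than the number of distinct labels")
      }
      labels <- c(seen, paste0("isolated_", seq_len(declared_n - n)))
      n <- declared_n
    } else {
      labels <- seen
    }
    ids_a <- match(a, seen)
    ids_b <- match(b, seen)
  }
  evsa_graph(cbind(ids_a, ids_b), n_nodes = n, labels = labels)
}

#' Write a graph as a whitespace-separated edge list
#'
#' Emits a `# nodes: N` header followed by one line per edge.  Graphs without
#' stored labels are written with 0-based integer ids.
#'
#' @param g an `evsa_graph`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "evsa_graph"))
  labels <- g$labels
  if (is.null(labels)) labels <- as.character(0:(g$n_nodes - 1L))
  lines <- sprintf("# nodes: %d", g$n_nodes)
  if (nrow(g$edges) > 0L) {
    lines <- c(lines, paste(labels[g$edges[, 1L]], labels[g$edges[, 2L]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Summary statistics of a graph
#'
#' Density is `2M / (N (N - 1))`, the fraction of realised node pairs;
#' the average degree is `2M / N`.  The latter is the preferred scale
#' parameter for comparing interaction networks of different sizes, since
#' density shrinks as `1/N` at a fixed average degree.
#'
#' @param g an `evsa_graph` with at least one node.
#' @return An object of class `evsa_graph_stats`: a list with `n_nodes`,
#'   `n_edges`, `density`, `avg_degree` and `degree_sequence`, all at full
#'   precision.  `format()` renders density truncated to 4 decimals and
#'   average degree rounded to 3, the convention used in published summary
#'   tables of the herpesvirus interaction networks.
#' @export
graph_stats <- function(g) {
  stopifnot(inherits(g, "evsa_graph"))
  n <- g$n_nodes
  if (n < 1L) stop("graph has no nodes")
  m <- nrow(g$edges)
  density <- if (n >= 2L) 2 * m / (n * (n - 1)) else 0
  structure(
    list(
      n_nodes = n,
      n_edges = m,
      density = density,
      avg_degree = 2 * m / n,
      degree_sequence = degree_sequence(g)
    ),
    class = "evsa_graph_stats"
  )
}

# truncate (not round) to `digits` decimals; guard against representation
# error pushing e.g. 1175.0 down to 1174
trunc_decimal <- function(x, digits) {
  trunc(x * 10^digits + 1e-9) / 10^digits
}

#' @export
format.evsa_graph_stats <- function(x, ...) {
  c(
    n_nodes = as.character(x$n_nodes),
    n_edges = as.character(x$n_edges),
    density = sprintf("%.4f", trunc_decimal(x$density, 4L)),
    avg_degree = sprintf("%.3f", round(x$avg_degree, 3L))
  )
}

#' @export
print.evsa_graph_stats <- function(x, ...) {
  f <- format(x)
  cat(sprintf(
    "Graph: %s nodes, %s edges, density %s, average degree %s\n",
    f[["n_nodes"]], f[["n_edges"]], f[["density"]], f[["avg_degree"]]
  ))
  invisible(x)
}

#' Connected components
#'
#' @param g an `evsa_graph`.
#' @return List of integer vectors, one per component, each sorted
#'   ascending; components ordered by their smallest member id.
#' @export
connected_components <- function(g) {
  stopifnot(inherits(g, "evsa_graph"))
  n <- g$n_nodes
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (nrow(g$edges) > 0L) {
    for (k in seq_len(nrow(g$edges))) {
      ri <- find(g$edges[k, 1L])
      rj <- find(g$edges[k, 2L])
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))
  comps <- split(seq_len(n), roots)
  comps <- unname(comps[order(vapply(comps, min, integer(1L)))])
  lapply(comps, as.integer)
}

# two-colouring check used by the spectral routines' test harness
is_bipartite <- function(g) {
  n <- g$n_nodes
  if (nrow(g$edges) == 0L) return(TRUE)
  adj <- vector("list", n)
  for (k in seq_len(nrow(g$edges))) {
    i <- g$edges[k, 1L]; j <- g$edges[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  colour <- rep(NA_integer_, n)
  for (s in seq_len(n)) {
    if (!is.na(colour[s])) next
    colour[s] <- 0L
    queue <- s
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.na(colour[w])) {
          colour[w] <- 1L - colour[v]
          queue <- c(queue, w)
        } else if (colour[w] == colour[v]) {
          return(FALSE)
        }
      }
    }
  }
  TRUE
}

# linear index of pair (i, j), i < j, among the n(n-1)/2 unordered pairs,
# enumerated row-major: (1,2), (1,3), ..., (1,n), (2,3), ...
pair_to_index <- function(i, j, n) {
  (i - 1) * n - i * (i + 1) / 2 + j
}

index_to_pair <- function(idx, n) {
  if (length(idx) == 0L) return(matrix(integer(0), ncol = 2L))
  # smallest i with cumulative pair count i*n - i(i+1)/2 >= idx
  i <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * idx))
  i <- pmax(i, 1)
  j <- idx - ((i - 1) * n - i * (i + 1) / 2)
  # guard against floating-point edge cases at block boundaries
  wrong <- j <= i | j > n
  while (any(wrong)) {
    i[wrong] <- i[wrong] + ifelse(j[wrong] <= i[wrong], -1, 1)
    j <- idx - ((i - 1) * n - i * (i + 1) / 2)
    wrong <- j <= i | j > n
  }
  cbind(as.integer(i), as.integer(j))
}

edge_indices <- function(g) {
  if (nrow(g$edges) == 0L) return(numeric(0))
  pair_to_index(g$edges[, 1L], g$edges[, 2L], g$n_nodes)
}
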