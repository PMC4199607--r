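# Counter-based child seeds: one user-facing seed deterministically expands
# into independent per-draw seeds, so individual replicates and experiment
# cells are reproducible in isolation.

#' Derive a child seed from a parent seed and counters
#'
#' Mixes the parent seed with a sequence of non-negative integer counters
#' through an LCG-style hash.  The result lies in `[0, 2^31 - 2]` and is
#' suitable for `set.seed()`.  All arithmetic stays below 2^53 so the hash is
#' exact in double precision.
#'
#' @param seed integer parent seed.
#' @param ... non-negative integer counters (e.g. cell index, replicate).
#' @return Integer child seed.
#' @examples
#' child_seed(1, 3, 7)
#' @export
child_seed <- function(seed, ...) {
  m <- 2147483647  # 2^31 - 1
  x <- as.numeric(seed) %% m
  ks <- c(...)
  for (k in c(0, as.numeric(ks))) {
    x <- (x * 69069 + k + 1013904223) %% m
    x <- (x * 69069 + 12345) %% m
  }
  as.integer(x %% (m - 1))
}

# evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}
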