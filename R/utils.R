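#' Evaluate an expression with a local, restorable RNG state
#'
#' All stochastic operations in dendrim take an explicit `seed` argument and
#' run under a local RNG so that they are reproducible and do not disturb the
#' caller's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Expand one global seed into deterministic per-stage seeds
#'
#' A whole pipeline run is reproducible from a single integer: each named
#' stage receives its own sub-seed drawn from a stream seeded by the global
#' one. Sub-seeds stay below 2^31.
#'
#' @param seed global integer seed.
#' @param stages character vector of stage names.
#' @return Named integer vector of per-stage seeds.
#' @export
#' @examples
#' derive_seeds(1, c("spines", "patterns"))
derive_seeds <- function(seed, stages) {
  stopifnot(is.character(stages), length(stages) >= 1)
  with_seed(seed, {
    s <- sample.int(.Machine$integer.max - 1L, length(stages))
    names(s) <- stages
    s
  })
}

# Disjoint-set forest with path compression and union by rank; used to count
# connected components of the waveform similarity graph.
uf_new <- function(n) {
  list(parent = seq_len(n), rank = integer(n))
}

uf_find <- function(uf, i) {
  root <- i
  while (uf$parent[root] != root) root <- uf$parent[root]
  while (uf$parent[i] != root) {   # path compression
    nxt <- uf$parent[i]
    uf$parent[i] <- root
    i <- nxt
  }
  list(uf = uf, root = root)
}

uf_union <- function(uf, i, j) {
  fi <- uf_find(uf, i); uf <- fi$uf
  fj <- uf_find(uf, j); uf <- fj$uf
  ri <- fi$root; rj <- fj$root
  if (ri == rj) return(uf)
  if (uf$rank[ri] < uf$rank[rj]) {
    uf$parent[ri] <- rj
  } else if (uf$rank[ri] > uf$rank[rj]) {
    uf$parent[rj] <- ri
  } else {
    uf$parent[rj] <- ri
    uf$rank[ri] <- uf$rank[ri] + 1L
  }
  uf
}

uf_components <- function(uf) {
  n <- length(uf$parent)
  roots <- integer(n)
  for (i in seq_len(n)) {
    f <- uf_find(uf, i); uf <- f$uf
    roots[i] <- f$root
  }
  roots
}

`%||%` <- function(a, b) if (is.null(a)) b else a
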