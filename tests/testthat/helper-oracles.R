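# Independent oracles, deliberately implemented with different algorithms
# than the package code they check.

# Brute-force BFS grouping of waveforms: components of the graph whose edges
# join rows differing in fewer than d quantized samples.
oracle_component_count <- function(values, d, step = 0.01) {
  q <- trunc(round(values / step, 6)) * step
  n <- nrow(q)
  if (n == 0) return(0L)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      adj[i, j] <- sum(q[i, ] != q[j, ]) < d
    }
  }
  seen <- rep(FALSE, n)
  comps <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comps <- comps + 1L
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
  }
  comps
}

# Branch enumeration oracle: groups dendritic edges by the end node reached
# when walking downstream to the next terminal or junction. Returns the
# multiset of branch lengths.
oracle_branch_lengths <- function(m) {
  n <- m$nodes
  dend <- !(n$structure %in% c(1L, 2L))
  pidx <- match(n$parent, n$id)
  is_child_edge <- dend & !is.na(pidx)
  kids <- lapply(seq_len(nrow(n)), function(i) which(is_child_edge & pidx == i))
  n_dkids <- lengths(kids)
  edge_len <- function(i) {
    p <- pidx[i]
    sqrt((n$x[i] - n$x[p])^2 + (n$y[i] - n$y[p])^2 + (n$z[i] - n$z[p])^2)
  }
  end_of <- function(i) {
    # walk down from dendritic node i to its branch end
    while (n_dkids[i] == 1L) i <- kids[[i]][1]
    i
  }
  ends <- vapply(which(is_child_edge), function(i) {
    # the branch of edge (parent(i), i) ends at the first terminal/junction
    # at or below i
    j <- i
    while (n_dkids[j] == 1L) j <- kids[[j]][1]
    n$id[j]
  }, integer(1))
  lens <- vapply(which(is_child_edge), edge_len, numeric(1))
  as.numeric(sort(tapply(lens, ends, sum)))
}

# Exact binomial coefficient through log-factorials plus integer rounding,
# cross-checked at small n against Pascal recursion.
oracle_choose <- function(n, k) {
  round(exp(lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)))
}

# Deterministic pairwise-discriminable template matrix for backend tests:
# K rows, each differing from every other in `width` samples.
make_test_templates <- function(K, n_samples, width) {
  stopifnot(width <= n_samples)
  tpl <- matrix(0.003, K, n_samples)
  for (t in seq_len(K)) tpl[t, seq_len(width)] <- 0.003 + t * 0.02
  tpl
}
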