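#' @title Statistical layer for comparative analyses
#' @description Permutation tests for correlation coefficients, unpaired
#'   rank-based group comparisons, min-max feature scaling of M, percent
#'   differences against a reference mean, and neuron-count weighting of
#'   species-level M averages.
#' @name stats-layer
NULL

#' Permutation test for a Pearson correlation
#'
#' `standard` mode (default) reports the usual two-sided permutation
#' p-value: the fraction of label shuffles whose `|R|` reaches the observed
#' `|R|`. `as_printed` mode implements the historical rule this framework
#' originally reported: count the fraction of shuffles whose correlation
#' exceeds 0.05 and reject the null when that fraction is below 0.05. The
#' printed rule degenerates for long vectors (a null correlation rarely
#' exceeds 0.05 at large N), which is why it is not the default.
#'
#' @param x,y equal-length numeric vectors (length >= 3, non-constant).
#' @param n_perm number of shuffles (default 10000).
#' @param mode `"standard"` or `"as_printed"`.
#' @param seed integer seed.
#' @return List with `R` (observed Pearson correlation), `p`, `reject`
#'   (decision at alpha = 0.05), `mode`, `n_perm`.
#' @export
perm_corr_test <- function(x, y, n_perm = 10000L,
                           mode = c("standard", "as_printed"), seed = 1L) {
  mode <- match.arg(mode)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  R <- stats::cor(x, y)
  perm_R <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    stats::cor(x, sample(y))
  }, numeric(1)))
  if (mode == "standard") {
    p <- mean(abs(perm_R) >= abs(R))
  } else {
    p <- mean(perm_R > 0.05)
  }
  list(R = R, p = p, reject = p < 0.05, mode = mode, n_perm = n_perm)
}

#' Rank-based group comparisons
#'
#' `ranksum` performs unpaired Wilcoxon rank-sum tests for every pair of
#' groups; `kruskal` performs a single k-group Kruskal-Wallis test.
#' Decisions at alpha = 0.05 are reported alongside the p-values.
#'
#' @param groups named list of numeric vectors, each nonempty.
#' @param test `"ranksum"` or `"kruskal"`.
#' @return For `ranksum`, a data.frame `(group1, group2, p, reject)`; for
#'   `kruskal`, a list with `statistic`, `p`, `reject`.
#' @export
group_compare <- function(groups, test = c("ranksum", "kruskal")) {
  test <- match.arg(test)
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes == 0)) {
    stop("empty group: ", paste(names(groups)[sizes == 0], collapse = ", "))
  }
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_along(groups))
  if (test == "kruskal") {
    kt <- stats::kruskal.test(groups)
    return(list(statistic = unname(kt$statistic), p = kt$p.value,
                reject = kt$p.value < 0.05))
  }
  pairs <- utils::combn(names(groups), 2)
  res <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    p = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    wt <- suppressWarnings(stats::wilcox.test(groups[[pairs[1, i]]],
                                              groups[[pairs[2, i]]]))
    res$p[i] <- wt$p.value
  }
  res$reject <- res$p < 0.05
  res
}

#' Min-max feature scaling
#'
#' Maps values into `[0, 1]`: `(v - min) / (max - min)`. Used to compare M
#' distributions of cells with very different sizes (the scaled quantity is
#' written M*).
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return Scaled vector in `[0, 1]`.
#' @export
feature_scale <- function(values) {
  rng <- range(values)
  if (diff(rng) == 0) stop("feature scaling undefined for constant input")
  (values - rng[1]) / diff(rng)
}

#' Signed percent difference against a reference mean
#'
#' @param group_mean group mean.
#' @param reference_mean nonzero reference (e.g. the grand mean).
#' @return `100 * (group_mean - reference_mean) / reference_mean`.
#' @export
percent_diff <- function(group_mean, reference_mean) {
  if (reference_mean == 0) stop("reference mean must be nonzero")
  100 * (group_mean - reference_mean) / reference_mean
}

#' Neuron-count-weighted species total
#'
#' Weights a species-average per-neuron discriminability by the total number
#' of neurons of that species' central nervous system, giving the total
#' recognizable-pattern capacity.
#'
#' @param mean_M species-average M (>= 0).
#' @param n_neurons total neuron count (>= 0).
#' @return Their product.
#' @export
#' @examples
#' format(weighted_species_total(245978, 8.5e10), scientific = TRUE)
weighted_species_total <- function(mean_M, n_neurons) {
  if (mean_M < 0 || n_neurons < 0) stop("arguments must be non-negative")
  mean_M * n_neurons
}

#' Group-wise comparison report
#'
#' Summarises a metadata table (one row per cell) into the report used for
#' cross-species / cross-type / cross-region comparisons: per-group mean and
#' SD of the value column, percent difference against the grand mean, an
#' unpaired rank-sum p-value of each group against all remaining cells, and
#' min-max scaled values.
#'
#' @param data data.frame of per-cell records.
#' @param value_col name of the numeric column to compare (default `"M"`).
#' @param group_col name of the grouping column.
#' @return List of class `comparison_report` with `groups` (data.frame:
#'   group, n, mean, sd, percent_diff, p, reject), `grand_mean`, and
#'   `scaled` (per-row M* in input order).
#' @export
comparison_report <- function(data, value_col = "M", group_col = "species") {
  if (!all(c(value_col, group_col) %in% names(data))) {
    stop("data must have columns ", value_col, " and ", group_col)
  }
  v <- data[[value_col]]
  g <- as.character(data[[group_col]])
  grand <- mean(v)
  levels <- sort(unique(g))
  rows <- lapply(levels, function(lev) {
    inside <- v[g == lev]
    outside <- v[g != lev]
    p <- if (length(outside) > 0) {
      suppressWarnings(stats::wilcox.test(inside, outside))$p.value
    } else NA_real_
    data.frame(group = lev, n = length(inside), mean = mean(inside),
               sd = stats::sd(inside),
               percent_diff = percent_diff(mean(inside), grand),
               p = p, stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, rows)
  groups$reject <- !is.na(groups$p) & groups$p < 0.05
  structure(list(groups = groups, grand_mean = grand,
                 scaled = feature_scale(v)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("<comparison_report> %d groups, grand mean = %.4g\n",
              nrow(x$groups), x$grand_mean))
  print(x$groups, row.names = FALSE)
  invisible(x)
}
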