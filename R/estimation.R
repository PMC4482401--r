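#' @title Stochastic estimation of the discriminable-pattern count M
#' @description Exhaustively enumerating coincident activation patterns is
#'   hopeless (a 40-spine branch probed at 7 activation points already has
#'   C(40,7) = 18,643,560 patterns), so M is estimated by a plateau search:
#'   batches of random patterns accumulate (10, 20, 30, ...), the
#'   discriminable count is recomputed after each batch, and the search stops
#'   when its discrete derivative is no longer positive. Per-neuron M is the
#'   sum over branches, and the per-branch values follow an
#'   `a*n*log(n) + b` law in the branch spine count n.
#' @name estimation
NULL

#' Estimate the discriminable-pattern count of one branch
#'
#' Runs the cumulative plateau search against a waveform backend (a function
#' mapping a list of activation patterns to a waveform matrix, e.g.
#' [make_surrogate_backend()]). Each random pattern activates `k_active`
#' spines chosen uniformly without replacement (k is capped at `n_spines`).
#' Rounds accumulate `batch_increment` new patterns; after each round M is
#' recomputed over all patterns generated so far, so the round-wise trace is
#' non-decreasing. The search continues while the discrete derivative
#' `D = M_t - M_(t-1)` is positive and stops when `D <= 0` or `max_rounds`
#' is reached, returning the maximum observed M.
#'
#' @param backend function `(patterns) -> waveform matrix`.
#' @param n_spines number of spines available on the branch (>= 1).
#' @param cfg an [estimation_config()].
#' @return List with `M` (maximum observed estimate), `trace` (per-round M),
#'   and `n_patterns` (patterns consumed).
#' @export
estimate_branch_M <- function(backend, n_spines, cfg = estimation_config()) {
  if (n_spines < 1) stop("n_spines must be >= 1")
  dcfg <- discriminability_config(cfg$d)
  draw_pattern <- function() {
    k <- if (identical(cfg$k_active, "uniform-random")) {
      sample.int(n_spines, 1)
    } else {
      min(as.integer(cfg$k_active), n_spines)
    }
    sort(sample.int(n_spines, k))
  }
  with_seed(cfg$seed, {
    waves <- NULL
    trace <- integer(0)
    prev_M <- NA_integer_
    for (round in seq_len(cfg$max_rounds)) {
      batch <- replicate(cfg$batch_increment, draw_pattern(), simplify = FALSE)
      new_waves <- backend(batch)
      waves <- rbind(waves, new_waves)
      M <- suppressWarnings(count_discriminable(waves, dcfg))$M
      trace <- c(trace, M)
      if (!is.na(prev_M) && (M - prev_M) <= 0L) break
      prev_M <- M
    }
    list(M = max(trace), trace = trace, n_patterns = nrow(waves))
  })
}

#' Estimate the discriminable-pattern count of a whole neuron
#'
#' Builds the spine map for the given biophysical parameters, runs the
#' plateau search on every branch carrying at least one spine (spineless
#' branches contribute 0), and sums: `M_total = sum over branches of M_b`.
#'
#' @param m a `morphology`.
#' @param params a [biophys_params()].
#' @param cfg an [estimation_config()]; per-branch pattern seeds are derived
#'   deterministically from `cfg$seed`.
#' @param sparams a [surrogate_params()].
#' @param timing a [waveform_timing()].
#' @param cuntz a [cuntz_params()].
#' @param max_branches optional cap on the number of branches processed (for
#'   desk-scale runs); remaining branches contribute 0.
#' @param progress function called with one message string per branch, or
#'   `NULL`.
#' @return List with `M_total` and `per_branch` data.frame
#'   `(branch_index, n_i, M)`.
#' @export
estimate_neuron_M <- function(m, params = biophys_params(),
                              cfg = estimation_config(),
                              sparams = surrogate_params(),
                              timing = waveform_timing(),
                              cuntz = cuntz_params(),
                              max_branches = NULL,
                              progress = NULL) {
  smap <- build_spine_map(m, params, cuntz, seed = cfg$seed)
  seeds <- derive_seeds(cfg$seed, paste0("branchM", seq_along(smap)))
  todo <- seq_along(smap)
  if (!is.null(max_branches)) todo <- utils::head(todo, max_branches)
  res <- data.frame(branch_index = vapply(smap, `[[`, integer(1), "branch_index"),
                    n_i = vapply(smap, `[[`, integer(1), "n_i"),
                    M = 0L)
  for (i in todo) {
    entry <- smap[[i]]
    if (entry$n_i < 1) next
    backend <- make_surrogate_backend(entry, params, sparams, timing)
    bcfg <- cfg
    bcfg$seed <- seeds[i]
    est <- estimate_branch_M(backend, entry$n_i, bcfg)
    res$M[i] <- est$M
    if (!is.null(progress)) {
      progress(sprintf("branch %d/%d: n_i = %d, M = %d",
                       i, length(smap), entry$n_i, est$M))
    }
  }
  list(M_total = sum(res$M), per_branch = res)
}

#' Predict neuron-level M from per-branch spine counts
#'
#' `M = sum_i (a * n_i * ln(n_i) + b)` with the convention that a spineless
#' branch (n_i = 0) contributes 0, not b: a branch without spines cannot
#' discriminate any pattern.
#'
#' @param spine_counts integer vector of per-branch spine counts.
#' @param a,b fitted law constants.
#' @return Predicted M (numeric).
#' @export
#' @examples
#' mlaw_predict(c(1), a = 3, b = 7)  # ln(1) = 0, so the branch contributes b
mlaw_predict <- function(spine_counts, a, b) {
  if (any(spine_counts < 0)) stop("spine counts must be >= 0")
  n <- spine_counts[spine_counts > 0]
  if (length(n) == 0) return(0)
  sum(a * n * log(n) + b)
}

#' Fit the per-branch M law
#'
#' Least-squares fit of per-branch `(n, M)` samples under one of three
#' candidate models: `nlogn` (`M = a*n*ln(n) + b`), `linear`
#' (`M = a*n + b`) or `quadratic` (`M = a*n^2 + b*n + c`), compared by
#' adjusted R^2 (`1 - (1 - R^2)(N - 1)/(N - p - 1)`, p = number of
#' coefficients excluding the intercept).
#'
#' The error of a stochastic per-branch M estimate scales with the estimate
#' itself (larger repertoires are probed with relatively sparser pattern
#' samples), so the default `error_model = "relative"` minimizes relative
#' residuals (weights `1/M^2`); `"additive"` is ordinary least squares.
#' The reported R^2 is always computed from unweighted residuals, so the two
#' error models are comparable.
#'
#' @param samples data.frame with columns `n` (spine count, >= 1) and `M`.
#' @param model_tag `"nlogn"`, `"linear"` or `"quadratic"`.
#' @param error_model `"relative"` (default) or `"additive"`.
#' @return Object of class `mlaw_fit`: list with `a`, `b` (and `c_` for the
#'   quadratic), `coefficients`, `adj_r2`, `model_tag`, `n_obs`.
#' @export
fit_mlaw <- function(samples, model_tag = c("nlogn", "linear", "quadratic"),
                     error_model = c("relative", "additive")) {
  model_tag <- match.arg(model_tag)
  error_model <- match.arg(error_model)
  if (!all(c("n", "M") %in% names(samples))) {
    stop("samples must have columns n and M")
  }
  samples <- samples[samples$n >= 1, , drop = FALSE]
  if (nrow(samples) < 3) stop("need at least 3 samples with n >= 1")
  if (length(unique(samples$n)) < 2) {
    stop("degenerate design: all spine counts identical")
  }
  fml <- switch(model_tag,
    nlogn = M ~ I(n * log(n)),
    linear = M ~ n,
    quadratic = M ~ I(n^2) + n)
  w <- if (error_model == "relative") {
    if (any(samples$M <= 0)) stop("relative error model needs positive M")
    1 / samples$M^2
  } else NULL
  fit <- stats::lm(fml, data = samples, weights = w)
  coefs <- stats::coef(fit)
  # adjusted R^2 on unweighted residuals: 1 - (1-R^2)(N-1)/(N-p-1),
  # p = coefficients excluding the intercept
  res <- samples$M - stats::fitted(fit)
  r2 <- 1 - sum(res^2) / sum((samples$M - mean(samples$M))^2)
  N <- nrow(samples)
  p <- length(coefs) - 1L
  adj <- 1 - (1 - r2) * (N - 1) / (N - p - 1)
  out <- list(model_tag = model_tag, coefficients = coefs,
              adj_r2 = adj, n_obs = nrow(samples))
  if (model_tag == "quadratic") {
    out$a <- unname(coefs[2]); out$b <- unname(coefs[3]); out$c_ <- unname(coefs[1])
  } else {
    out$a <- unname(coefs[2]); out$b <- unname(coefs[1])
  }
  structure(out, class = "mlaw_fit")
}

#' @export
print.mlaw_fit <- function(x, ...) {
  cat(sprintf("<mlaw_fit> %s: a = %.4g, b = %.4g, adj R^2 = %.4f (N = %d)\n",
              x$model_tag, x$a, x$b, x$adj_r2, x$n_obs))
  invisible(x)
}

#' Generate synthetic per-branch law samples
#'
#' Draws branch spine counts uniformly from `n_range` (desk-scale cortical
#' branches carry from a handful to a few dozen spines) and per-branch M
#' values from the `a*n*ln(n) + b` law with multiplicative Gaussian noise,
#' emulating the error structure of stochastic plateau estimates.
#'
#' @param n_branches number of samples.
#' @param a,b law constants.
#' @param noise_sd multiplicative noise standard deviation (e.g. 0.05).
#' @param n_range integer range of spine counts.
#' @param seed integer seed.
#' @return data.frame with columns `n` and `M`.
#' @export
gen_mlaw_samples <- function(n_branches = 100, a = 2, b = 5, noise_sd = 0.05,
                             n_range = c(2L, 60L), seed = 1L) {
  with_seed(seed, {
    n <- sample(seq(n_range[1], n_range[2]), n_branches, replace = TRUE)
    M <- (a * n * log(n) + b) * (1 + noise_sd * stats::rnorm(n_branches))
    data.frame(n = n, M = M)
  })
}

#' Write a fitted M law as a small JSON report
#'
#' @param fit an [fit_mlaw()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mlaw_json <- function(fit, path) {
  jsonlite::write_json(
    list(model = fit$model_tag, a = fit$a, b = fit$b,
         adj_r2 = fit$adj_r2, n_obs = fit$n_obs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
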