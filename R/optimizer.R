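#' @title Genetic-algorithm tuning of biophysical parameters
#' @description Most biophysical parameters of a reconstructed cell are
#'   inaccessible; the framework therefore searches the restricted
#'   five-dimensional grid (resting potential, spine spatial mode, density
#'   setting, AMPA and NMDA fractions) for the combination that maximizes
#'   the discriminable-pattern count M, using a simple generational scheme:
#'   select the two best candidates, uniform crossover, per-coordinate
#'   mutation with low probability, and replacement of the two worst.
#' @name optimizer
NULL

.param_names <- c("v_rest", "spatial_mode", "density_setting",
                  "ampa_fraction", "nmda_fraction")

.candidate_key <- function(cand) {
  paste(vapply(.param_names, function(p) format(cand[[p]], digits = 15),
               character(1)), collapse = "|")
}

.random_candidate <- function(space) {
  out <- lapply(space, function(grid) grid[[sample.int(length(grid), 1)]])
  out[.param_names]
}

#' Genetic-algorithm search over a parameter space
#'
#' Per iteration: evaluate the pool (with per-tuple caching, since M
#' estimation is the cost center and tuples recur on small grids), select
#' the two best, produce two offspring by uniform crossover (each of the
#' five coordinates swapped between the parents with probability 1/2),
#' mutate each coordinate with probability `mutation_prob` (redrawn
#' uniformly from its grid), and replace the two worst candidates, keeping
#' the pool size constant. The global best over all evaluated candidates is
#' tracked separately, so the returned optimum never degrades even though
#' offspring replace the worst unconditionally.
#'
#' @param objective function taking a named parameter list (fields of
#'   [biophys_params()]) and returning a numeric score to maximize.
#' @param space a [parameter_space()].
#' @param cfg a [ga_config()].
#' @return List with `best` (named parameter list), `best_value`, `history`
#'   (data.frame: iteration, pool_best, global_best), and `n_evaluated`
#'   (distinct tuples evaluated).
#' @export
ga_optimize <- function(objective, space, cfg = ga_config()) {
  stopifnot(inherits(space, "parameter_space"), inherits(cfg, "ga_config"))
  cache <- new.env(parent = emptyenv())
  best <- NULL
  best_value <- -Inf
  evaluate <- function(cand) {
    key <- .candidate_key(cand)
    if (!is.null(cache[[key]])) return(cache[[key]])
    val <- objective(cand)
    if (!is.finite(val) && !identical(val, -Inf)) {
      stop("objective returned a non-finite value for candidate ", key)
    }
    cache[[key]] <- val
    if (val > best_value) {
      best_value <<- val
      best <<- cand
    }
    val
  }
  mutate <- function(cand) {
    for (p in .param_names) {
      if (stats::runif(1) < cfg$mutation_prob) {
        grid <- space[[p]]
        cand[[p]] <- grid[[sample.int(length(grid), 1)]]
      }
    }
    cand
  }
  crossover <- function(p1, p2) {
    for (p in .param_names) {
      if (stats::runif(1) < 0.5) {
        tmp <- p1[[p]]; p1[[p]] <- p2[[p]]; p2[[p]] <- tmp
      }
    }
    list(p1, p2)
  }
  with_seed(cfg$seed, {
    pool <- replicate(cfg$pool_size, .random_candidate(space), simplify = FALSE)
    values <- vapply(pool, evaluate, numeric(1))
    history <- data.frame(iteration = seq_len(cfg$iterations),
                          pool_best = NA_real_, global_best = NA_real_)
    for (it in seq_len(cfg$iterations)) {
      ord <- order(values, decreasing = TRUE)
      parents <- crossover(pool[[ord[1]]], pool[[ord[2]]])
      off1 <- mutate(parents[[1]])
      off2 <- mutate(parents[[2]])
      v1 <- evaluate(off1); v2 <- evaluate(off2)
      worst <- utils::tail(ord, 2)
      pool[[worst[1]]] <- off1; values[worst[1]] <- v1
      pool[[worst[2]]] <- off2; values[worst[2]] <- v2
      history$pool_best[it] <- max(values)
      history$global_best[it] <- best_value
    }
    list(best = best, best_value = best_value, history = history,
         n_evaluated = length(ls(cache)))
  })
}

#' Exhaustively evaluate a parameter space
#'
#' Brute-force reference for small grids: evaluates every point and returns
#' the argmax. Complements [ga_optimize()] as an oracle on spaces of a few
#' hundred points.
#'
#' @param objective as in [ga_optimize()].
#' @param space a [parameter_space()].
#' @return List with `best`, `best_value`.
#' @export
exhaustive_optimize <- function(objective, space) {
  grid <- expand.grid(lapply(space, seq_along))
  best <- NULL; best_value <- -Inf
  for (r in seq_len(nrow(grid))) {
    cand <- lapply(.param_names, function(p) space[[p]][[grid[r, p]]])
    names(cand) <- .param_names
    val <- objective(cand)
    if (val > best_value) { best_value <- val; best <- cand }
  }
  list(best = best, best_value = best_value)
}

#' Optimize the biophysical parameters of one neuron
#'
#' Runs [ga_optimize()] with per-neuron M estimation
#' ([estimate_neuron_M()]) as the objective and reports the result as one
#' record in the layout of the optimized-cell tables: cell id, v_rest, SP
#' (LS/UN), rho (in CL multiples), AMPA, NMDA (fractions), M.
#'
#' @param m a `morphology`.
#' @param cell_id character label for the record.
#' @param space a [parameter_space()].
#' @param cfg a [ga_config()].
#' @param est_cfg an [estimation_config()].
#' @param sparams a [surrogate_params()].
#' @param timing a [waveform_timing()].
#' @param cuntz a [cuntz_params()].
#' @param max_branches optional per-candidate branch cap for desk-scale runs.
#' @return One-row data.frame `(cell, v_rest, SP, rho, AMPA, NMDA, M)`.
#' @export
optimize_neuron <- function(m, cell_id = "cell", space = parameter_space(),
                            cfg = ga_config(), est_cfg = estimation_config(),
                            sparams = surrogate_params(),
                            timing = waveform_timing(),
                            cuntz = cuntz_params(), max_branches = NULL) {
  objective <- function(cand) {
    params <- biophys_params(v_rest = cand$v_rest,
                             spatial_mode = cand$spatial_mode,
                             density_setting = cand$density_setting,
                             ampa_fraction = cand$ampa_fraction,
                             nmda_fraction = cand$nmda_fraction)
    estimate_neuron_M(m, params, est_cfg, sparams, timing, cuntz,
                      max_branches = max_branches)$M_total
  }
  res <- ga_optimize(objective, space, cfg)
  b <- res$best
  data.frame(cell = cell_id, v_rest = b$v_rest,
             SP = if (b$spatial_mode == "linspace") "LS" else "UN",
             rho = b$density_setting, AMPA = b$ampa_fraction,
             NMDA = b$nmda_fraction, M = res$best_value,
             stringsAsFactors = FALSE)
}
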