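#' Biophysical parameter tuple
#'
#' The five tunable parameters of the framework: membrane resting potential,
#' spine spatial distribution, spine density setting (multiplier of the
#' Cuntz-law density, CL), and AMPA/NMDA receptor fractions.
#'
#' @param v_rest membrane resting potential, mV.
#' @param spatial_mode `"linspace"` (equidistant) or `"uniform"`.
#' @param density_setting multiplier of the Cuntz-law density (1 = CL,
#'   0.5 = CL/2, 2 = 2CL).
#' @param ampa_fraction,nmda_fraction fraction of spines carrying each
#'   receptor (1 = every spine, "NS"; 0.5 = half, "NS/2").
#' @return List of class `biophys_params`.
#' @export
biophys_params <- function(v_rest = -80, spatial_mode = c("linspace", "uniform"),
                           density_setting = 1, ampa_fraction = 1,
                           nmda_fraction = 0.5) {
  spatial_mode <- match.arg(spatial_mode)
  if (density_setting <= 0) stop("density_setting must be positive")
  if (ampa_fraction < 0 || ampa_fraction > 1 ||
      nmda_fraction < 0 || nmda_fraction > 1) {
    stop("receptor fractions must lie in [0, 1]")
  }
  structure(list(v_rest = v_rest, spatial_mode = spatial_mode,
                 density_setting = density_setting,
                 ampa_fraction = ampa_fraction, nmda_fraction = nmda_fraction),
            class = "biophys_params")
}

#' Waveform discriminability configuration
#'
#' Two equal-length quantized waveforms are discriminable when they differ in
#' at least `d` sample points. The default `d = 400` corresponds to a 10 ms
#' window at the default sampling step of 25 us.
#'
#' @param d integer sample-count threshold (>= 1).
#' @return List of class `discriminability_config`.
#' @export
discriminability_config <- function(d = 400L) {
  d <- as.integer(d)
  if (d < 1) stop("d must be >= 1")
  structure(list(d = d), class = "discriminability_config")
}

#' Waveform timing configuration
#'
#' @param dt sampling step, ms (default 0.025 ms = 25 us).
#' @param duration trace duration, ms (default 200 ms, i.e. 8000 samples).
#' @param release_time synaptic release time, ms (default 50 ms).
#' @return List of class `waveform_timing` with derived sample count
#'   `n_samples`.
#' @export
waveform_timing <- function(dt = 0.025, duration = 200, release_time = 50) {
  if (dt <= 0 || duration <= 0) stop("dt and duration must be positive")
  if (release_time < 0 || release_time >= duration) {
    stop("release_time must lie in [0, duration)")
  }
  n <- duration / dt
  if (abs(n - round(n)) > 1e-9) stop("duration must be a multiple of dt")
  structure(list(dt = dt, duration = duration, release_time = release_time,
                 n_samples = as.integer(round(n))),
            class = "waveform_timing")
}

#' Plateau-search (stochastic M estimation) configuration
#'
#' @param batch_increment activation patterns added per round (default 10,
#'   giving the 10/20/30/... cumulative schedule).
#' @param k_active spines activated per random pattern: a positive integer
#'   (capped at the branch spine count; default 7, the toy-example probe
#'   size) or `"uniform-random"` to draw k afresh for every pattern.
#' @param max_rounds safeguard on the number of rounds (default 100).
#' @param seed integer seed for pattern generation.
#' @param d discriminability threshold in samples, see
#'   [discriminability_config()].
#' @return List of class `estimation_config`.
#' @export
estimation_config <- function(batch_increment = 10L, k_active = 7L,
                              max_rounds = 100L, seed = 1L, d = 400L) {
  batch_increment <- as.integer(batch_increment)
  if (batch_increment < 1) stop("batch_increment must be >= 1")
  if (!(identical(k_active, "uniform-random") || (is.numeric(k_active) && k_active >= 1))) {
    stop("k_active must be a positive integer or \"uniform-random\"")
  }
  if (max_rounds < 2) stop("max_rounds must be >= 2 (the derivative needs two rounds)")
  structure(list(batch_increment = batch_increment, k_active = k_active,
                 max_rounds = as.integer(max_rounds), seed = as.integer(seed),
                 d = as.integer(d)),
            class = "estimation_config")
}

#' Genetic-algorithm configuration
#'
#' @param pool_size candidate pool size, kept constant across iterations
#'   (default 100; must be >= 4 for best-2/worst-2 bookkeeping).
#' @param iterations number of GA iterations (default 500).
#' @param mutation_prob per-parameter mutation probability (default 0.1).
#' @param seed integer seed.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(pool_size = 100L, iterations = 500L,
                      mutation_prob = 0.1, seed = 1L) {
  if (pool_size < 4) stop("pool_size must be >= 4")
  if (mutation_prob < 0 || mutation_prob > 1) stop("mutation_prob must lie in [0, 1]")
  if (iterations < 1) stop("iterations must be >= 1")
  structure(list(pool_size = as.integer(pool_size),
                 iterations = as.integer(iterations),
                 mutation_prob = mutation_prob, seed = as.integer(seed)),
            class = "ga_config")
}

#' Five-dimensional biophysical parameter space
#'
#' Finite grids for the five tunable parameters. Defaults reconstruct the
#' values observed in optimized cells (v_rest around -78..-82 mV, linspace
#' vs uniform placement, CL multiples, NS / NS/2 receptor settings),
#' modestly extended.
#'
#' @param v_rest numeric grid of resting potentials, mV.
#' @param spatial_mode character grid of placement modes.
#' @param density_setting numeric grid of CL multipliers.
#' @param ampa_fraction,nmda_fraction numeric grids of receptor fractions.
#' @return List of class `parameter_space`.
#' @export
parameter_space <- function(v_rest = -85:-75,
                            spatial_mode = c("linspace", "uniform"),
                            density_setting = c(0.5, 1, 2),
                            ampa_fraction = c(0.25, 0.5, 0.75, 1),
                            nmda_fraction = c(0.25, 0.5, 0.75, 1)) {
  space <- list(v_rest = v_rest, spatial_mode = spatial_mode,
                density_setting = density_setting,
                ampa_fraction = ampa_fraction, nmda_fraction = nmda_fraction)
  if (any(vapply(space, length, integer(1)) == 0)) {
    stop("all parameter grids must be nonempty")
  }
  structure(space, class = "parameter_space")
}

#' Number of points in a parameter space
#' @param space a [parameter_space()].
#' @return Integer grid size.
#' @export
space_size <- function(space) {
  prod(vapply(space, length, integer(1)))
}
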