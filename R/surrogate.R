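#' @title Surrogate somatic-EPSP simulator
#' @description A deterministic, configurable stand-in biophysical model that
#'   maps a coincident activation pattern on a branch to a somatic voltage
#'   trace. Each active AMPA-flagged spine contributes a fast
#'   double-exponential kernel and each NMDA-flagged spine a slow one whose
#'   amplitude grows sigmoidally with the number of co-active NMDA spines in
#'   a local spatial window (the supralinear synaptic-clustering effect);
#'   contributions are attenuated by `exp(-x/lambda)` with arc-length
#'   distance x to the branch origin, and NMDA gain increases with membrane
#'   hyperpolarization. Kernel constants are artifact parameters of this
#'   surrogate, inspired by the behaviour of detailed compartmental models,
#'   not measured quantities.
#' @name surrogate
NULL

#' Surrogate kernel parameters
#'
#' @param ampa_amp,ampa_tau_rise,ampa_tau_decay AMPA kernel peak amplitude
#'   (mV) and time constants (ms).
#' @param nmda_amp,nmda_tau_rise,nmda_tau_decay NMDA kernel peak amplitude
#'   (mV) and time constants (ms).
#' @param lambda passive attenuation length constant along the branch, um.
#' @param cluster_window spatial window for counting co-active NMDA spines,
#'   um.
#' @param cluster_threshold,cluster_slope,cluster_gain sigmoid parameters of
#'   the supralinear NMDA amplification: gain = 1 + cluster_gain *
#'   logistic((k - threshold)/slope) for k co-active NMDA spines in the
#'   window.
#' @param v_opt,v_width,nmda_vgain_max NMDA amplitude is further multiplied
#'   by the voltage gain `1 + nmda_vgain_max * exp(-(v_rest - v_opt)^2 /
#'   (2 v_width^2))`: relative to a depolarized rest (around -75 mV),
#'   hyperpolarization increases the NMDA contribution and hence the number
#'   of patterns the cell discriminates, but the dependence is bell-shaped
#'   around `v_opt` (default -81 mV) -- the net effect of Mg2+ block relief
#'   against glutamatergic driving force -- so the optimum resting potential
#'   sits inside the hyperpolarized band rather than at a grid corner.
#' @return List of class `surrogate_params`.
#' @export
surrogate_params <- function(ampa_amp = 0.30, ampa_tau_rise = 0.2,
                             ampa_tau_decay = 2,
                             nmda_amp = 0.50, nmda_tau_rise = 3,
                             nmda_tau_decay = 40,
                             lambda = 200, cluster_window = 10,
                             cluster_threshold = 3, cluster_slope = 1,
                             cluster_gain = 2,
                             v_opt = -81, v_width = 3, nmda_vgain_max = 1) {
  structure(as.list(environment()), class = "surrogate_params")
}

#' Activation pattern on a branch
#'
#' @param branch_index branch identifier.
#' @param active_spines integer vector of activated spine indices on that
#'   branch.
#' @param release_time synaptic release time, ms.
#' @return List of class `activation_pattern`.
#' @export
activation_pattern <- function(branch_index, active_spines, release_time = 50) {
  structure(list(branch_index = branch_index,
                 active_spines = as.integer(active_spines),
                 release_time = release_time),
            class = "activation_pattern")
}

# unit-peak double-exponential kernel on the time axis t (ms), onset t0
.dexp_kernel <- function(t, t0, tau_rise, tau_decay) {
  s <- t - t0
  out <- numeric(length(t))
  on <- s >= 0
  tpeak <- tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
  peak <- exp(-tpeak / tau_decay) - exp(-tpeak / tau_rise)
  out[on] <- (exp(-s[on] / tau_decay) - exp(-s[on] / tau_rise)) / peak
  out
}

#' Simulate a somatic waveform for one activation pattern
#'
#' Deterministic given its inputs: the same pattern always yields the same
#' trace. The trace sits at `v_rest` before release.
#'
#' @param spine_entry one entry of a [build_spine_map()] (fields `positions`,
#'   `ampa`, `nmda`, `n_i`).
#' @param pattern an [activation_pattern()]; `active_spines` must index
#'   existing spines of the entry.
#' @param params a [biophys_params()] (only `v_rest` is used here; placement
#'   and receptor assignment are already frozen in the spine map).
#' @param sparams a [surrogate_params()].
#' @param timing a [waveform_timing()]; `pattern$release_time` overrides the
#'   timing's release time.
#' @return Numeric vector of length `timing$n_samples` (mV).
#' @export
surrogate_simulate <- function(spine_entry, pattern,
                               params = biophys_params(),
                               sparams = surrogate_params(),
                               timing = waveform_timing()) {
  act <- pattern$active_spines
  if (length(act) > 0 && (min(act) < 1 || max(act) > spine_entry$n_i)) {
    stop("active spine index outside the branch (n_i = ", spine_entry$n_i, ")")
  }
  if (pattern$release_time >= timing$duration) {
    stop("release_time must precede the end of the trace")
  }
  t <- (seq_len(timing$n_samples) - 1) * timing$dt
  v <- rep(params$v_rest, timing$n_samples)
  if (length(act) == 0) return(v)
  pos <- spine_entry$positions[act]
  ampa <- spine_entry$ampa[act]
  nmda <- spine_entry$nmda[act]
  atten <- exp(-pos / sparams$lambda)
  vgain <- 1 + sparams$nmda_vgain_max *
    exp(-(params$v_rest - sparams$v_opt)^2 / (2 * sparams$v_width^2))
  kernA <- .dexp_kernel(t, pattern$release_time,
                        sparams$ampa_tau_rise, sparams$ampa_tau_decay)
  kernN <- .dexp_kernel(t, pattern$release_time,
                        sparams$nmda_tau_rise, sparams$nmda_tau_decay)
  nmda_pos <- pos[nmda]
  for (s in seq_along(act)) {
    if (ampa[s]) v <- v + sparams$ampa_amp * atten[s] * kernA
    if (nmda[s]) {
      k <- sum(abs(nmda_pos - pos[s]) <= sparams$cluster_window)
      gain <- 1 + sparams$cluster_gain *
        stats::plogis((k - sparams$cluster_threshold) / sparams$cluster_slope)
      v <- v + sparams$nmda_amp * atten[s] * gain * vgain * kernN
    }
  }
  v
}

#' Waveform backend over a spine-map entry
#'
#' Wraps [surrogate_simulate()] into the backend interface consumed by
#' [estimate_branch_M()]: a function that maps a list of activation patterns
#' (integer vectors of active spine indices) to a waveform matrix, one row
#' per pattern.
#'
#' @param spine_entry one entry of a [build_spine_map()].
#' @param params a [biophys_params()].
#' @param sparams a [surrogate_params()].
#' @param timing a [waveform_timing()].
#' @return Function `(patterns) -> matrix`.
#' @export
make_surrogate_backend <- function(spine_entry, params = biophys_params(),
                                   sparams = surrogate_params(),
                                   timing = waveform_timing()) {
  force(spine_entry); force(params); force(sparams); force(timing)
  function(patterns) {
    out <- matrix(0, nrow = length(patterns), ncol = timing$n_samples)
    for (i in seq_along(patterns)) {
      pat <- activation_pattern(spine_entry$branch_index, patterns[[i]],
                                release_time = timing$release_time)
      out[i, ] <- surrogate_simulate(spine_entry, pat, params, sparams, timing)
    }
    out
  }
}

#' Enumerable cycling backend (test double)
#'
#' A backend whose producible repertoire is exactly the supplied template
#' set: successive calls cycle deterministically through the templates in
#' order, regardless of the patterns' content. Useful for validating the
#' plateau estimator against a backend of known repertoire size, and for
#' scripting repertoire-growth scenarios via `schedule`.
#'
#' @param templates numeric matrix of pairwise-discriminable template
#'   waveforms (rows).
#' @param schedule optional integer vector: template index to emit at each
#'   successive call position (recycled); default cycles 1..K.
#' @return Function `(patterns) -> matrix`, stateful across calls.
#' @export
make_cycling_backend <- function(templates, schedule = NULL) {
  templates <- as.matrix(templates)
  K <- nrow(templates)
  if (is.null(schedule)) schedule <- seq_len(K)
  counter <- 0L
  function(patterns) {
    n <- length(patterns)
    idx <- schedule[(counter + seq_len(n) - 1L) %% length(schedule) + 1L]
    counter <<- counter + n
    templates[idx, , drop = FALSE]
  }
}
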