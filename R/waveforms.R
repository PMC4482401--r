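#' @title Somatic waveform sets and the discriminability criterion
#' @description A waveform set is a matrix of somatic voltage traces (mV),
#'   one per activation pattern, sampled at a fixed dt over a fixed duration
#'   (defaults: 25 us and 200 ms, N = 8000 samples). Traces are truncated to
#'   the second decimal digit (10 uV, the precision of patch-clamp
#'   recordings) before comparison; two traces are discriminable when they
#'   differ in at least d quantized samples (default d = 400, a 10 ms
#'   window). The number of discriminable waveforms M in a set is the number
#'   of connected components of the similarity graph, counted with a
#'   disjoint-set forest.
#' @name waveforms
NULL

#' Construct a waveform set
#'
#' @param values numeric matrix, one waveform per row (mV), or a single
#'   numeric vector.
#' @param timing a [waveform_timing()]; row length must equal
#'   `timing$n_samples`.
#' @param quantization_step quantization cell width, mV (default 0.01 =
#'   10 uV).
#' @return Matrix of class `waveform_set` with timing attributes.
#' @export
waveform_set <- function(values, timing = waveform_timing(),
                         quantization_step = 0.01) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix (waveforms in rows)")
  }
  if (ncol(values) != timing$n_samples) {
    stop("waveform length ", ncol(values), " does not match timing (",
         timing$n_samples, " samples)")
  }
  structure(values, class = c("waveform_set", "matrix"),
            timing = timing, quantization_step = quantization_step)
}

#' Quantize a waveform to recording precision
#'
#' Values are truncated toward zero to two decimal digits of mV (10 uV
#' resolution): `12.349999 -> 12.34`, `-80.119 -> -80.11`. Truncation (not
#' rounding) mirrors dropping the unreliable digits of a noisy recording;
#' the toward-zero direction makes the rule the plain string truncation of
#' the decimal expansion for either sign. Idempotent.
#'
#' @param w numeric vector or matrix of voltages (mV).
#' @param step quantization cell width, mV.
#' @return Quantized object of the same shape.
#' @export
quantize <- function(w, step = 0.01) {
  if (any(!is.finite(w))) stop("waveform values must be finite")
  # round at 1e-6 of a cell first so that values intended to sit exactly on
  # a cell boundary are not pushed down by binary representation error
  trunc(round(w / step, 6)) * step
}

#' Count differing samples between two quantized waveforms
#'
#' @param w,z equal-length numeric vectors (quantized; [quantize()] is
#'   applied defensively, it is idempotent).
#' @return Integer count of sample positions with unequal quantized values.
#' @export
n_differing <- function(w, z) {
  if (length(w) != length(z)) {
    stop("waveforms have different lengths (", length(w), " vs ", length(z), ")")
  }
  sum(quantize(w) != quantize(z))
}

#' Are two waveforms discriminable?
#'
#' True iff the quantized traces differ in at least `d` sample points.
#'
#' @param w,z equal-length waveforms.
#' @param cfg a [discriminability_config()].
#' @return Logical.
#' @export
is_discriminable <- function(w, z, cfg = discriminability_config()) {
  n_differing(w, z) >= cfg$d
}

#' Count discriminable waveforms in a set
#'
#' Builds the similarity graph (edge between two waveforms iff they are NOT
#' discriminable, i.e. differ in fewer than `d` quantized samples) and
#' returns the number of its connected components, computed with a
#' disjoint-set forest with union by rank. In the ideal case the components
#' are disjoint complete graphs; when real traces are not transitive the
#' component count is still returned and a warning reports the fraction of
#' intra-component pairs that are discriminable.
#'
#' @param ws a [waveform_set()] or plain numeric matrix (waveforms in rows).
#' @param cfg a [discriminability_config()].
#' @return List with `M` (number of discriminable waveforms), `labels`
#'   (component id per waveform; each component is labelled by its lowest
#'   member index), and `non_transitive_fraction`.
#' @export
count_discriminable <- function(ws, cfg = discriminability_config()) {
  if (is.null(dim(ws))) ws <- matrix(ws, nrow = 1)
  n <- nrow(ws)
  if (n == 0) return(list(M = 0L, labels = integer(0), non_transitive_fraction = 0))
  q <- quantize(unclass(ws))
  uf <- uf_new(n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      wi <- q[i, ]
      for (j in seq(i + 1, n)) {
        if (sum(wi != q[j, ]) < cfg$d) uf <- uf_union(uf, i, j)
      }
    }
  }
  roots <- uf_components(uf)
  # label each component by its lowest member index
  labels <- stats::ave(seq_len(n), roots, FUN = min)
  M <- length(unique(labels))
  # non-transitivity diagnostic: discriminable pairs inside a component
  bad <- 0L; intra <- 0L
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      wi <- q[i, ]
      for (j in seq(i + 1, n)) {
        if (labels[i] == labels[j]) {
          intra <- intra + 1L
          if (sum(wi != q[j, ]) >= cfg$d) bad <- bad + 1L
        }
      }
    }
  }
  frac <- if (intra > 0) bad / intra else 0
  if (frac > 0) {
    warning(sprintf(
      "similarity graph is not transitive: %.1f%% of intra-component pairs are discriminable",
      100 * frac))
  }
  list(M = as.integer(M), labels = as.integer(labels),
       non_transitive_fraction = frac)
}

#' Generate a template-based synthetic waveform set
#'
#' Emulates a recording session in which a branch expresses a small number
#' of distinct somatic waveform shapes: `n_templates` template traces that
#' pairwise differ in at least `separation` samples, each copied
#' `n_per_template` times with sub-quantization noise, so that
#' [count_discriminable()] regroups the set into exactly `n_templates`
#' classes whenever `separation >= d`.
#'
#' Templates are constant-offset deflections positioned at quantization-cell
#' midpoints; the noise amplitude must stay below 0.007 mV so that no noisy
#' copy crosses a truncation boundary.
#'
#' @param n_templates number of distinct shapes.
#' @param n_per_template copies per shape.
#' @param separation number of samples on which templates differ (must not
#'   exceed the trace length).
#' @param noise_amplitude uniform noise amplitude, mV (in `[0, 0.007)`).
#' @param seed integer seed.
#' @param timing a [waveform_timing()].
#' @return A [waveform_set()] of `n_templates * n_per_template` rows, with
#'   attribute `template_id`.
#' @export
#' @examples
#' ws <- gen_waveform_templates(3, 5, separation = 40, noise_amplitude = 0.003,
#'                              seed = 1, timing = waveform_timing(dt = 1, duration = 100))
#' count_discriminable(ws, discriminability_config(d = 10))$M  # 3
gen_waveform_templates <- function(n_templates, n_per_template, separation,
                                   noise_amplitude = 0.003, seed = 1L,
                                   timing = waveform_timing()) {
  N <- timing$n_samples
  if (n_templates < 1 || n_per_template < 1) {
    stop("n_templates and n_per_template must be >= 1")
  }
  if (separation < 1 || separation > N) {
    stop("separation must lie in [1, trace length]")
  }
  if (noise_amplitude < 0 || noise_amplitude >= 0.007) {
    stop("noise_amplitude must stay below the quantization cell (< 0.007 mV)")
  }
  base <- 0.003  # cell midpoint offset: truncation-safe under the noise bound
  values <- matrix(base, nrow = n_templates * n_per_template, ncol = N)
  template_id <- rep(seq_len(n_templates), each = n_per_template)
  for (t in seq_len(n_templates)) {
    # distinct quantization cell per template over the first `separation` samples
    level <- base + t * 0.02
    values[template_id == t, seq_len(separation)] <- level
  }
  if (noise_amplitude > 0) {
    noise <- with_seed(seed, matrix(
      stats::runif(length(values), 0, noise_amplitude),
      nrow = nrow(values)))
    values <- values + noise
  }
  ws <- waveform_set(values, timing)
  attr(ws, "template_id") <- template_id
  ws
}

#' Write a waveform set as CSV
#'
#' One waveform per row; a header comment records dt and duration so traces
#' can be exchanged with an external NEURON run of the exported bundle.
#'
#' @param ws a [waveform_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_waveforms_csv <- function(ws, path) {
  timing <- attr(ws, "timing")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt_ms=%g duration_ms=%g release_ms=%g",
                     timing$dt, timing$duration, timing$release_time), con)
  utils::write.table(unclass(ws), con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a waveform set from CSV
#'
#' @param path CSV written by [write_waveforms_csv()].
#' @return A [waveform_set()].
#' @export
read_waveforms_csv <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header, regexec(
    "dt_ms=([0-9.eE+-]+) duration_ms=([0-9.eE+-]+) release_ms=([0-9.eE+-]+)",
    header))[[1]]
  if (length(m) != 4) stop("missing dt/duration header in ", path)
  timing <- waveform_timing(dt = as.numeric(m[2]), duration = as.numeric(m[3]),
                            release_time = as.numeric(m[4]))
  vals <- as.matrix(utils::read.table(path, sep = ",", comment.char = "#"))
  dimnames(vals) <- NULL
  waveform_set(vals, timing)
}
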