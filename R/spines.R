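#' @title Spine allocation from the Cuntz scaling law
#' @description The scaling law \eqn{L = c \, n^{2/3} V^{1/3}} relates total
#'   dendritic wiring length L, synapse count n and dendrite volume V.
#'   Inverting it gives the putative spine count of a reconstruction,
#'   \eqn{n = (L / (c V^{1/3}))^{3/2}}, which is then distributed over
#'   branches in proportion to branch length and placed either equidistantly
#'   or uniformly at random.
#' @name spines
NULL

# Default proportionality constant, calibrated once on the packaged
# synthetic_cortical_suite() so the suite's mean spine density matches the
# literature mouse-cortical mean of 1.54 spines/um (plausible range
# 0.5-2.1 spines/um). See the methods vignette.
.default_cuntz_c <- 0.7554

#' Cuntz-law parameters
#'
#' @param c proportionality constant of the scaling law (> 0). The default is
#'   calibrated on [synthetic_cortical_suite()] to a mean spine density of
#'   1.54 spines/um.
#' @param density_multiplier multiplier applied to the law's density (the rho
#'   setting): 0.5 for CL/2, 1 for CL, 2 for 2CL.
#' @return List of class `cuntz_params`.
#' @export
cuntz_params <- function(c = .default_cuntz_c, density_multiplier = 1) {
  if (c <= 0) stop("c must be positive")
  if (density_multiplier <= 0) stop("density_multiplier must be positive")
  structure(list(c = c, density_multiplier = density_multiplier),
            class = "cuntz_params")
}

#' Putative spine count of a dendritic tree
#'
#' Inverts the scaling law: `n = round(rho * (L / (c * V^(1/3)))^(3/2))`.
#'
#' @param L total dendritic length, um (>= 0).
#' @param V total dendritic volume, um^3 (> 0 whenever L > 0).
#' @param params a [cuntz_params()] object.
#' @return Integer spine count; 0 when L = 0.
#' @export
#' @examples
#' cuntz_spine_count(4, 1, cuntz_params(c = 1))  # 4^(3/2) = 8
cuntz_spine_count <- function(L, V, params = cuntz_params()) {
  stopifnot(inherits(params, "cuntz_params"))
  if (L < 0) stop("L must be non-negative")
  if (L == 0) return(0L)
  if (V <= 0) stop("V must be positive when L > 0")
  n <- params$density_multiplier * (L / (params$c * V^(1 / 3)))^(3 / 2)
  as.integer(round(n))
}

#' Allocate spines to branches in proportion to branch length
#'
#' Fractional allocations `n_total * l_b / L` are rounded with the
#' largest-remainder method (ties broken by branch index) so the total is
#' conserved exactly.
#'
#' @param n_total total spine count (>= 0).
#' @param branches list of branches from [dissect_branches()], or a numeric
#'   vector of branch lengths.
#' @return Integer vector of per-branch counts summing to `n_total`.
#' @export
allocate_spines <- function(n_total, branches) {
  if (n_total < 0) stop("n_total must be >= 0")
  lens <- if (is.numeric(branches)) branches else
    vapply(branches, function(b) b$length, numeric(1))
  if (length(lens) == 0) {
    if (n_total > 0) stop("cannot allocate spines to an empty branch list")
    return(integer(0))
  }
  L <- sum(lens)
  if (L <= 0) stop("total branch length must be positive")
  frac <- n_total * lens / L
  base <- floor(frac)
  left <- as.integer(round(n_total - sum(base)))
  counts <- as.integer(base)
  if (left > 0) {
    rem <- frac - base
    take <- order(-rem, seq_along(rem))[seq_len(left)]
    counts[take] <- counts[take] + 1L
  }
  counts
}

#' Place spines along a branch
#'
#' `linspace` places spines at midpoints `(j - 1/2) * l_b / n_i`, giving a
#' constant inter-spine distance `l_b / n_i` (inversely proportional to the
#' density) without colliding with branch endpoints. `uniform` draws i.i.d.
#' uniform arc-length positions on `[0, l_b]` and sorts them.
#'
#' @param l_b branch length, um.
#' @param n_i spine count (>= 0).
#' @param mode `"linspace"` or `"uniform"`.
#' @param seed integer seed (used by `"uniform"`).
#' @return Sorted numeric vector of arc-length positions in `[0, l_b]`.
#' @export
place_spines <- function(l_b, n_i, mode = c("linspace", "uniform"),
                         seed = NULL) {
  mode <- match.arg(mode)
  if (n_i < 0) stop("n_i must be >= 0")
  if (n_i == 0) return(numeric(0))
  if (mode == "linspace") {
    (seq_len(n_i) - 0.5) * l_b / n_i
  } else {
    with_seed(seed, sort(stats::runif(n_i, 0, l_b)))
  }
}

#' Assign AMPA/NMDA receptor flags to spines
#'
#' Exactly `floor(fraction * n_i)` spines receive each receptor; a fraction
#' of 1 flags every spine deterministically, otherwise the flagged subset is
#' chosen uniformly at random (seeded).
#'
#' @param n_i spine count.
#' @param ampa_fraction,nmda_fraction fractions in `[0, 1]`.
#' @param seed integer seed.
#' @return List with logical vectors `ampa` and `nmda` of length `n_i`.
#' @export
assign_receptors <- function(n_i, ampa_fraction = 1, nmda_fraction = 0.5,
                             seed = NULL) {
  if (ampa_fraction < 0 || ampa_fraction > 1 ||
      nmda_fraction < 0 || nmda_fraction > 1) {
    stop("receptor fractions must lie in [0, 1]")
  }
  pick <- function(fraction, sub_seed) {
    k <- floor(fraction * n_i)
    flags <- rep(FALSE, n_i)
    if (k >= n_i) {
      flags[] <- TRUE
    } else if (k > 0) {
      idx <- with_seed(sub_seed, sample.int(n_i, k))
      flags[idx] <- TRUE
    }
    flags
  }
  seeds <- if (is.null(seed)) c(NULL, NULL) else derive_seeds(seed, c("ampa", "nmda"))
  list(ampa = pick(ampa_fraction, if (is.null(seed)) NULL else seeds[["ampa"]]),
       nmda = pick(nmda_fraction, if (is.null(seed)) NULL else seeds[["nmda"]]))
}

#' Exact binomial coefficient
#'
#' The number of coincident activation patterns of `k` active spines among
#' `n` is `C(n, k)`; this is the combinatorial count that motivates the
#' stochastic plateau search (e.g. `C(40, 7)` = 18,643,560 already for a
#' single 40-spine branch probed at 7 activation points).
#'
#' @param n,k non-negative integers with `k <= n`.
#' @return Exact integer value (as a double for large results; exact below
#'   2^53).
#' @export
count_combinations <- function(n, k) {
  if (n < 0 || k < 0) stop("n and k must be non-negative")
  if (k > n) stop("k must not exceed n")
  k <- min(k, n - k)
  if (k == 0) return(1)
  # incremental product keeps every intermediate an exact integer
  out <- 1
  for (i in seq_len(k)) out <- out * (n - k + i) / i
  round(out)
}

#' Build a spine map for a morphology
#'
#' Runs the full allocation pipeline: total spine count from the Cuntz law,
#' proportional allocation over branches, spatial placement, and receptor
#' assignment.
#'
#' @param m a `morphology`.
#' @param params a [biophys_params()] object (spatial mode, density setting,
#'   receptor fractions).
#' @param cuntz a [cuntz_params()] object; its `density_multiplier` is
#'   overridden by `params$density_setting`.
#' @param seed integer seed.
#' @return Object of class `spine_map`: list of entries
#'   `(branch_index, n_i, l_b, positions, ampa, nmda)`, one per branch, plus
#'   attribute `n_total`.
#' @export
build_spine_map <- function(m, params = biophys_params(), cuntz = cuntz_params(),
                            seed = 1L) {
  stopifnot(inherits(m, "morphology"), inherits(params, "biophys_params"))
  cuntz$density_multiplier <- params$density_setting
  st <- morpho_stats(m)
  branches <- dissect_branches(m)
  n_total <- cuntz_spine_count(st$total_length, st$total_volume, cuntz)
  counts <- allocate_spines(n_total, branches)
  seeds <- derive_seeds(seed, paste0("branch", seq_along(branches)))
  entries <- vector("list", length(branches))
  for (i in seq_along(branches)) {
    b <- branches[[i]]
    sub <- derive_seeds(seeds[i], c("place", "receptors"))
    pos <- place_spines(b$length, counts[i], mode = params$spatial_mode,
                        seed = sub[["place"]])
    rec <- assign_receptors(counts[i], params$ampa_fraction,
                            params$nmda_fraction, seed = sub[["receptors"]])
    entries[[i]] <- list(branch_index = b$branch_index, n_i = counts[i],
                         l_b = b$length, positions = pos,
                         ampa = rec$ampa, nmda = rec$nmda)
  }
  structure(entries, class = "spine_map", n_total = n_total)
}

#' @export
print.spine_map <- function(x, ...) {
  cat(sprintf("<spine_map> %d spines over %d branches\n",
              attr(x, "n_total"), length(x)))
  invisible(x)
}

#' Mean spine density implied by the Cuntz law on a set of morphologies
#'
#' @param morphologies list of `morphology` objects.
#' @param cuntz a [cuntz_params()] object.
#' @return Numeric vector of per-cell densities (spines/um).
#' @export
spine_densities <- function(morphologies, cuntz = cuntz_params()) {
  vapply(morphologies, function(m) {
    st <- morpho_stats(m)
    cuntz_spine_count(st$total_length, st$total_volume, cuntz) / st$total_length
  }, numeric(1))
}
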