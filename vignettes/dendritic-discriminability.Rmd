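---
title: "Methods: estimating dendritic input-pattern discriminability from morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating dendritic input-pattern discriminability from morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrim)
```

`dendrim` estimates **M**, the number of coincident synaptic input patterns a
dendritic tree can discriminate through its somatic voltage waveforms, using
only information derivable from an SWC reconstruction plus a small set of
tunable biophysical parameters. This vignette is the package's own account of
the method: the model and its assumptions, the parameters that matter, what
the synthetic generators do and do not emulate, and the numerical choices
made where the design was genuinely open.

## 1. From morphology to spines

An SWC reconstruction is a rooted tree of 3D points with radii. Soma
(structure code 1) and axon (code 2) nodes are retained for geometry but
excluded from dendritic accounting; all remaining structure codes (basal and
apical dendrites alike) are pooled — reconstructions rarely annotate
dendrite subtype consistently enough to separate them. A *branch* is a
maximal unbranched path between the root (or the attachment point on the
soma), a branch point, and a terminal; the stem up to the first branch point
counts as a branch, so a binary tree with *p* bifurcations has 2*p* + 1
branches. Total length *L* sums Euclidean parent–child distances; total
volume *V* sums conical-frustum volumes π·h·(r₁² + r₁r₂ + r₂²)/3. Edges are
attributed to their child node's structure, so the soma-to-dendrite
attachment edge counts as dendritic — the convention keeps the branch
partition exact (branch lengths sum to *L* to within 1e−9 relative).

The spine count comes from the scaling law *L = c·n^(2/3)·V^(1/3)*, inverted
to

> n = round(ρ · (L / (c · V^(1/3)))^(3/2)),

with ρ a density multiplier (1 = the law's own density "CL", 0.5 = "CL/2",
...). The proportionality constant *c* is dimensionless and configurable; its
default (0.7554) was calibrated **once** on the packaged
`synthetic_cortical_suite()` so that the suite's mean density equals the
literature mouse-cortical mean of 1.54 spines/µm, and was not revisited. On
that suite the implied densities span roughly 1.3–1.9 spines/µm, inside the
commonly cited plausible range 0.5–2.1.

Spines are allocated to branches proportionally to branch length, with
largest-remainder rounding (ties broken by branch index) so totals are
conserved exactly. Placement is either *equidistant* (`linspace`, positions
(j − ½)·l_b/n_i — midpoints rather than endpoints, to avoid collisions with
branch points while keeping the constant spacing l_b/n_i) or *uniform*
(i.i.d. on [0, l_b], sorted, seeded). Receptor assignment flags exactly
floor(fraction·n_i) spines per receptor — the floor never exceeds the spine
count — choosing the subset uniformly at random unless the fraction is 1, in
which case every spine is flagged deterministically.

## 2. Waveforms and the discriminability criterion

Somatic traces are sampled for 200 ms at dt = 25 µs (N = 8000 points;
synaptic release at 50 ms) and truncated — not rounded — to the second
decimal digit of mV, i.e. 10 µV, the precision floor of typical patch-clamp
recordings. Truncation is *toward zero* for either sign (the plain string
truncation of the decimal expansion); `floor` would differ at negative
voltages, which is why the direction is fixed explicitly. A guard rounding at
10⁻⁶ of a cell is applied before truncating so values sitting exactly on a
cell boundary are not pushed into the lower cell by binary representation
error. Quantization happens *before* differences are computed, since its
rationale is recording noise.

Two equal-length quantized traces are **discriminable** when they differ in
at least *d* sample points; d = 400 (10 ms) by default, and M shrinks as *d*
grows. The number of discriminable waveforms in a set is the number of
connected components of the similarity graph (edge = *not* discriminable),
maintained with a disjoint-set forest with union by rank and path
compression. In the ideal case components are disjoint complete graphs; real
trace sets need not be transitive, so the component count is returned
regardless and a warning reports the fraction of intra-component pairs that
are discriminable. Component labels (lowest member index) are returned so the
similarity structure stays inspectable.

## 3. The surrogate simulator

Running a detailed compartmental model is outside this package's scope;
instead a deterministic surrogate maps an activation pattern to a somatic
trace, and an exporter writes the standard NEURON input bundle so the same
spine maps can drive an external detailed model. The surrogate is a sum of
unit-peak double-exponential kernels: AMPA (τ_rise 0.2 ms, τ_decay 2 ms, peak
0.30 mV) and NMDA (3 ms / 40 ms, peak 0.50 mV) per active flagged spine, each
attenuated by exp(−x/λ) for arc-length distance x to the branch origin
(λ = 200 µm). Two nonlinearities carry the biology that matters for
discriminability:

* **Cluster supralinearity** — each NMDA contribution is scaled by
  1 + 2·logistic(k − 3), with k the number of co-active NMDA spines within a
  10 µm window, so the k-th clustered spine adds strictly more than the
  (k−1)-th around the threshold.
* **Voltage gain** — NMDA amplitudes are multiplied by
  1 + exp(−(v_rest + 81)²/(2·3²)): hyperpolarizing from −75 mV increases the
  NMDA deflection, but the dependence is bell-shaped (Mg²⁺-block relief
  against driving force), so the optimal resting potential is an interior
  point near −81 mV rather than a grid corner.

All kernel constants are artifact parameters of the surrogate
(`surrogate_params()`), chosen to behave like detailed models of thin
cortical dendrites; they are not measured quantities, and nothing downstream
depends on their exact values beyond the qualitative shape just described.

## 4. Plateau estimation and the M law

Enumerating activation patterns is infeasible (C(n, k) explodes), so M is
estimated stochastically. Random patterns activate k spines chosen uniformly
without replacement; k defaults to 7 (capped at the branch spine count) —
the probe size of the worked toy example — and is configurable, including a
`"uniform-random"` mode, because no single k is canonical for production
runs. Batches of 10 patterns accumulate (10, 20, 30, ...; cumulative rather
than independent, matching the monotone-growth assumption that a larger
pattern set can only expose more of the repertoire), M is recomputed over all
patterns after each batch, and the search stops when the discrete derivative
M_t − M_(t−1) is ≤ 0, returning the maximum observed M. A `max_rounds`
safeguard (default 100) bounds pathological backends. The estimator never
exceeds the backend's true repertoire size; it can stop one round early when
a batch happens to add no new shape, which is the price of the plateau
heuristic rather than a defect.

Per-neuron M sums the branch values; spineless branches contribute 0. The
per-branch law is

> M(n) = a·n·ln n + b,

with natural log (a and b absorb base changes) and the convention that
n = 0 contributes 0, not b — an inactive branch cannot discriminate
anything, and fits use spiny branches only. `fit_mlaw()` compares the n·ln n,
linear and quadratic forms by adjusted R² = 1 − (1 − R²)(N − 1)/(N − p − 1)
(p = coefficients excluding the intercept). Because stochastic plateau
estimates err multiplicatively (larger repertoires are probed relatively more
sparsely), the default fit minimizes *relative* residuals (weights 1/M²);
ordinary least squares is available as `error_model = "additive"`. Adjusted
R² is always computed from unweighted residuals so the two error models are
comparable. Under plain OLS the intercept of the n·ln n law is essentially
unidentifiable at 5% multiplicative noise — its absolute standard error
scales with the largest M in the sample — which is the concrete reason the
relative fit is the default.

## 5. Genetic-algorithm tuning

Five parameters are tuned on a finite grid: v_rest (default −85…−75 mV,
1 mV steps), spatial mode {linspace, uniform}, density setting
{0.5, 1, 2}·CL, and AMPA/NMDA fractions {0.25, 0.5, 0.75, 1}. The GA keeps a
constant pool (default 100) over 500 iterations: evaluate, select the best
two, uniform crossover (each coordinate swapped with probability ½ — the
tuple is unordered, so uniform crossover is the unbiased choice), mutate each
coordinate with probability 0.1 (redrawn from its grid), and replace the two
worst unconditionally. The global best over all evaluated candidates is
tracked separately, so the returned optimum never degrades even under the
literal worst-replacement policy. Objective values are cached by parameter
tuple; on small grids the cache turns the nominal 100×500 evaluations into at
most one per grid point, and the initial pool is drawn uniformly from the
grids. On every grid we test (up to 500 points) the GA recovers the
exhaustive optimum across 20 seeds.

## 6. Statistics

Correlations are tested by permutation. The default (`standard`) p-value is
the fraction of label shuffles whose |R| reaches the observed |R|; it is
calibrated (type-I error ≈ α on null simulations). The historical
`as_printed` rule — count shuffles whose correlation exceeds 0.05 and reject
when that fraction is below 0.05 — is implemented verbatim for fidelity but
degenerates for long vectors (a null correlation rarely exceeds a fixed 0.05
at large N), so it is not the default. Group comparisons use the *unpaired*
Wilcoxon rank-sum test (the comparisons actually performed are unpaired;
pairwise over groups) or Kruskal–Wallis for k groups, at α = 0.05 with no
multiple-testing correction. M values are made comparable across cells by
min–max feature scaling to [0, 1] (M*), group means are summarised as signed
percent differences against the grand mean, and species totals weight the
per-neuron average by the species' total neuron count.

## 7. Synthetic data: what it emulates, what it does not

Three generators make every stage testable offline:

* `gen_synthetic_morphology()` grows random binary trees with an exact
  bifurcation count, gamma-distributed branch lengths (CV 0.3) and linearly
  tapering radii. It emulates the *statistics* the pipeline consumes (branch
  counts, lengths, calibres) but not real arbor geometry: no space-filling
  constraints, no subtype structure, no reconstruction artifacts.
  `synthetic_cortical_suite()` fixes a 12-cell, mouse-cortical-like
  configuration (10–40 bifurcations, 25–60 µm mean branch length, 0.3–0.95 µm
  calibres) used for density calibration.
* `gen_waveform_templates()` builds sets of known regrouping structure:
  shapes at quantization-cell midpoints separated in ≥ `separation` samples,
  copies jittered by sub-quantization noise (< 0.007 mV, so no copy crosses a
  truncation boundary). It emulates the *counting problem*, not EPSP shapes.
* `gen_mlaw_samples()` draws branch spine counts uniformly in [2, 60] (the
  per-branch range the fixture suite actually produces) and M values from the
  law with multiplicative Gaussian noise.

Passing tests therefore demonstrate the correctness of the machinery —
parsing, partitioning, allocation, counting, plateau logic, GA optimality,
fitting — under controlled conditions; they do not validate the surrogate's
biophysics against recordings, nor the law's constants on real
reconstructions.

## 8. Numerical choices and degenerate inputs

* Multi-root SWC files are rejected (single-cell reconstructions have one
  root); dangling parents, duplicate ids, non-positive radii and cycles are
  structural errors, malformed lines report their line number.
* Empty patterns yield a flat trace at v_rest; empty waveform sets have
  M = 0; constant vectors are errors for correlation and feature scaling, as
  is a degenerate all-equal-n design for fitting.
* All stochastic operations take an explicit seed and run under a local RNG
  (`with_seed`), leaving the caller's random stream untouched; one global
  seed expands deterministically into named per-stage seeds (`derive_seeds`),
  so a whole pipeline run is reproducible from one integer.
* Exact integer arithmetic for binomial coefficients uses the incremental
  product (every intermediate is an integer), exact below 2^53 — far above
  any count the framework feeds into it.

Test and acceptance runs use reduced problem sizes chosen as the package's
own desk-scale defaults: traces of 50–100 ms at dt = 0.25–1 ms for
estimation tests (with *d* rescaled to the same relative window), the
production 8000-sample timing for the 208-waveform regrouping check, tiny
parameter grids with capped branch counts for end-to-end GA runs. Full-scale
runs (8000-sample traces over every branch of large arbors, 100×500 GA
schedules) are supported by the same code paths but are long; `cmd_estimate`
streams per-branch progress and honours `max_branches` for partial runs.

## 9. Known limitations

* The surrogate is qualitative: absolute M values depend on its kernel
  constants and on *d*; only comparisons under fixed settings are meaningful.
* The plateau estimator is a lower-bound-biased point estimate; no
  uncertainty is attached.
* The Cuntz constant *c* is calibrated on synthetic fixtures, not fitted to
  data; analyses of real reconstructions should treat it as a free setting
  and check density plausibility.
* Receptor placement ignores spine geometry and co-location constraints
  beyond the per-branch fractions.
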