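#' Export a NEURON-compatible input-file bundle
#'
#' Writes the four plain-text inputs a compartmental simulation of the cell
#' consumes: `neuron_reconstruction.hoc` (the cell geometry, one section per
#' dendritic branch with `pt3dadd` points), `biophysical_model.hoc`
#' (membrane parameters), `synapses_specs.hoc` (receptor kinetics), and
#' `synapses_locs.dat` (one synapse per line: branch index, normalized
#' arc-length position, AMPA flag, NMDA flag). The number of `.dat` records
#' equals the total spine count of the map.
#'
#' @param m a `morphology`.
#' @param spine_map a [build_spine_map()] result whose positions lie on
#'   `m`'s branches.
#' @param params a [biophys_params()].
#' @param dir output directory (created if absent).
#' @return Character vector of the four file paths, invisibly.
#' @export
export_neuron_bundle <- function(m, spine_map, params = biophys_params(),
                                 dir) {
  stopifnot(inherits(m, "morphology"), inherits(spine_map, "spine_map"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  branches <- dissect_branches(m)
  if (length(spine_map) != length(branches)) {
    stop("spine map does not match the morphology's branches")
  }
  nodes <- m$nodes
  paths <- file.path(dir, c("neuron_reconstruction.hoc",
                            "biophysical_model.hoc",
                            "synapses_specs.hoc",
                            "synapses_locs.dat"))
  # geometry
  geo <- c(sprintf("// generated by dendrim"),
           sprintf("create soma, dend[%d]", length(branches)),
           "soma { pt3dclear()")
  soma <- nodes[nodes$structure == 1L, , drop = FALSE]
  if (nrow(soma) == 0) soma <- nodes[nodes$parent == -1L, , drop = FALSE]
  geo <- c(geo, sprintf("  pt3dadd(%.6f, %.6f, %.6f, %.6f)",
                        soma$x, soma$y, soma$z, 2 * soma$radius), "}")
  for (b in branches) {
    idx <- match(b$node_path, nodes$id)
    geo <- c(geo,
             sprintf("dend[%d] { pt3dclear()", b$branch_index - 1L),
             sprintf("  pt3dadd(%.6f, %.6f, %.6f, %.6f)",
                     nodes$x[idx], nodes$y[idx], nodes$z[idx],
                     2 * nodes$radius[idx]),
             "}")
  }
  writeLines(geo, paths[1])
  # membrane / biophysics
  writeLines(c("// generated by dendrim",
               sprintf("v_init = %.2f", params$v_rest),
               "forall { insert pas  g_pas = 1e-4  e_pas = v_init }",
               "celsius = 34"), paths[2])
  # synapse kinetics
  writeLines(c("// generated by dendrim",
               "// AMPA: fast double-exponential conductance",
               "AMPA_tau1 = 0.2  // ms",
               "AMPA_tau2 = 2    // ms",
               "// NMDA: slow, voltage-dependent conductance",
               "NMDA_tau1 = 3    // ms",
               "NMDA_tau2 = 40   // ms"), paths[3])
  # synapse locations: one record per spine
  recs <- character(0)
  for (e in spine_map) {
    if (e$n_i == 0) next
    norm <- if (e$l_b > 0) e$positions / e$l_b else e$positions
    recs <- c(recs, sprintf("%d %.6f %d %d", e$branch_index, norm,
                            as.integer(e$ampa), as.integer(e$nmda)))
  }
  writeLines(recs, paths[4])
  invisible(paths)
}

#' Read back a synapse-location table
#'
#' @param path a `synapses_locs.dat` written by [export_neuron_bundle()].
#' @return data.frame `(branch_index, position, ampa, nmda)`; empty for an
#'   empty file.
#' @export
read_synapse_locs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0 || length(readLines(path, warn = FALSE)) == 0) {
    return(data.frame(branch_index = integer(0), position = numeric(0),
                      ampa = logical(0), nmda = logical(0)))
  }
  tab <- utils::read.table(path)
  data.frame(branch_index = as.integer(tab[[1]]), position = tab[[2]],
             ampa = tab[[3]] == 1, nmda = tab[[4]] == 1)
}
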