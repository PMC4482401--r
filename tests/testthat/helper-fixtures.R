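# In-code fixtures shared across test files.

swc_file <- function(lines) {
  f <- tempfile(fileext = ".swc")
  writeLines(lines, f)
  f
}

# root -> child -> child chain along z, dendritic (code 3), unit radii
chain_swc <- function(n_nodes = 3, spacing = 10) {
  lines <- sprintf("%d 3 0 0 %g 1 %d", seq_len(n_nodes),
                   (seq_len(n_nodes) - 1) * spacing,
                   c(-1L, seq_len(n_nodes - 1)))
  swc_file(lines)
}

# soma root with one stem that bifurcates into two daughters
bifurcation_swc <- function() {
  swc_file(c(
    "1 1 0 0 0 5 -1",
    "2 3 0 0 10 1 1",
    "3 3 0 0 20 1 2",
    "4 3 5 0 30 1 3",
    "5 3 -5 0 30 1 3"
  ))
}

# a full binary dendritic tree with p junctions, built from the generator
binary_tree <- function(p, seed = 1) {
  gen_synthetic_morphology(p, mean_branch_length = 30,
                           radius_range = c(0.4, 0.8), seed = seed)
}

small_timing <- function() waveform_timing(dt = 0.5, duration = 50, release_time = 10)

fixture_swc_path <- function() {
  system.file("extdata", "synthetic_cell.swc", package = "dendrim")
}
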