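test_that("read_swc parses minimal files and validates structure", {
  m <- read_swc(chain_swc(3))
  expect_s3_class(m, "morphology")
  expect_equal(nrow(m$nodes), 3)
  expect_length(dissect_branches(m), 1)

  # malformed line reports its line number
  bad <- swc_file(c("1 3 0 0 0 1 -1", "2 3 0 0"))
  expect_error(read_swc(bad), "line 2")

  # dangling parent
  dangling <- swc_file(c("1 3 0 0 0 1 -1", "5 3 0 0 1 1 99"))
  expect_error(read_swc(dangling), "absent parent 99")

  # multiple roots rejected
  multi <- swc_file(c("1 3 0 0 0 1 -1", "2 3 1 0 0 1 -1"))
  expect_error(read_swc(multi), "multiple roots")

  # non-positive radius rejected
  zr <- swc_file(c("1 3 0 0 0 0 -1"))
  expect_error(read_swc(zr), "radii")
})

test_that("SWC write/read round-trip is lossless at printed precision", {
  m <- gen_synthetic_morphology(3, 30, c(0.4, 0.8), seed = 11)
  f1 <- tempfile(fileext = ".swc"); f2 <- tempfile(fileext = ".swc")
  write_swc(m, f1)
  m2 <- read_swc(f1)
  write_swc(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(m2$nodes$x, round(m$nodes$x, 6))
  expect_equal(m2$nodes$radius, round(m$nodes$radius, 6))
})

test_that("branch dissection matches hand counts and the DFS oracle", {
  # unbranched chain: one branch
  expect_length(dissect_branches(read_swc(chain_swc(10))), 1)

  # stem + bifurcation: 3 branches (stem counts as a branch)
  m <- read_swc(bifurcation_swc())
  br <- dissect_branches(m)
  expect_length(br, 3)
  # stem: soma -> node 3 (includes the soma attachment edge)
  expect_equal(sort(vapply(br, function(b) length(b$node_path), integer(1))),
               c(2, 2, 3))

  # full binary trees: 2p + 1 branches, lengths agree with the edge-walking
  # oracle
  for (p in c(0, 2, 5, 9)) {
    mt <- binary_tree(p, seed = p + 1)
    brt <- dissect_branches(mt)
    expect_length(brt, 2 * p + 1)
    expect_equal(sort(vapply(brt, `[[`, numeric(1), "length")),
                 oracle_branch_lengths(mt), tolerance = 1e-12)
  }
})

test_that("branch lengths partition the total dendritic length", {
  for (seed in 1:5) {
    m <- gen_synthetic_morphology(sample(0:12, 1), 35, c(0.3, 0.9), seed = seed)
    st <- morpho_stats(m)
    br <- dissect_branches(m)
    expect_equal(sum(vapply(br, `[[`, numeric(1), "length")), st$total_length,
                 tolerance = 1e-9)
    expect_equal(sum(vapply(br, `[[`, numeric(1), "volume")), st$total_volume,
                 tolerance = 1e-9)
  }
})

test_that("morpho_stats computes Euclidean lengths and frustum volumes", {
  # 3-4-5 triangle edge
  m <- morphology(data.frame(id = 1:2, structure = 3L,
                             x = c(0, 3), y = c(0, 4), z = 0,
                             radius = 1, parent = c(-1L, 1L)))
  st <- morpho_stats(m)
  expect_equal(st$total_length, 5)
  # cylinder: r1 = r2 = 1, h = 5 -> V = 5*pi
  expect_equal(st$total_volume, 5 * pi)

  # unit cylinder
  m2 <- morphology(data.frame(id = 1:2, structure = 3L,
                              x = c(0, 0), y = 0, z = c(0, 1),
                              radius = 1, parent = c(-1L, 1L)))
  expect_equal(morpho_stats(m2)$total_volume, pi)

  # additivity: two subtrees hanging off one soma sum their stats
  soma <- data.frame(id = 1L, structure = 1L, x = 0, y = 0, z = 0,
                     radius = 5, parent = -1L)
  sub1 <- data.frame(id = 2:3, structure = 3L, x = 0, y = 0, z = c(5, 10),
                     radius = 1, parent = c(1L, 2L))
  sub2 <- data.frame(id = 4:5, structure = 3L, x = c(3, 6), y = 0, z = 0,
                     radius = 0.5, parent = c(1L, 4L))
  both <- morpho_stats(morphology(rbind(soma, sub1, sub2)))
  only1 <- morpho_stats(morphology(rbind(soma, sub1)))
  only2 <- morpho_stats(morphology(rbind(soma, sub2)))
  expect_equal(both$total_length, only1$total_length + only2$total_length)
  expect_equal(both$total_volume, only1$total_volume + only2$total_volume)
})

test_that("soma and axon nodes are excluded from dendritic accounting", {
  m <- morphology(data.frame(
    id = 1:4, structure = c(1L, 2L, 3L, 3L),
    x = c(0, 10, 0, 0), y = 0, z = c(0, 0, 5, 12),
    radius = c(5, 0.5, 1, 1), parent = c(-1L, 1L, 1L, 3L)))
  st <- morpho_stats(m)
  # axon edge (10 um) not counted; dendrite: soma->3 (5) + 3->4 (7)
  expect_equal(st$total_length, 12)
  expect_equal(st$n_branches, 1)
})

test_that("synthetic morphology generator is seeded and obeys the 2p+1 rule", {
  m0 <- gen_synthetic_morphology(0, 40, c(0.3, 0.8), seed = 5)
  expect_length(dissect_branches(m0), 1)
  m5 <- gen_synthetic_morphology(5, 40, c(0.3, 0.8), seed = 5)
  expect_length(dissect_branches(m5), 11)

  f1 <- tempfile(); f2 <- tempfile()
  write_swc(gen_synthetic_morphology(4, 40, c(0.3, 0.8), seed = 9), f1)
  write_swc(gen_synthetic_morphology(4, 40, c(0.3, 0.8), seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(gen_synthetic_morphology(2, -1, c(0.3, 0.8), seed = 1),
               "positive")
})

test_that("NEURON bundle export writes four files with conserved synapse counts", {
  m <- read_swc(bifurcation_swc())
  p <- biophys_params()
  smap <- build_spine_map(m, p, cuntz_params(c = 0.2), seed = 1)
  n_total <- attr(smap, "n_total")
  expect_gt(n_total, 0)
  dir <- tempfile(); dir.create(dir)
  paths <- export_neuron_bundle(m, smap, p, dir)
  expect_true(all(file.exists(paths)))
  expect_identical(basename(paths),
                   c("neuron_reconstruction.hoc", "biophysical_model.hoc",
                     "synapses_specs.hoc", "synapses_locs.dat"))
  locs <- read_synapse_locs(file.path(dir, "synapses_locs.dat"))
  expect_equal(nrow(locs), n_total)
  expect_true(all(locs$position >= 0 & locs$position <= 1))
  # re-parse reproduces normalized positions to 6 decimals
  want <- unlist(lapply(smap, function(e) if (e$n_i > 0) e$positions / e$l_b else numeric(0)))
  expect_equal(locs$position, round(want, 6), tolerance = 5e-7)
})

test_that("NEURON bundle export handles an empty spine map", {
  m <- read_swc(chain_swc(4))
  p <- biophys_params()
  # huge c -> zero spines
  smap <- build_spine_map(m, p, cuntz_params(c = 1e6), seed = 1)
  expect_equal(attr(smap, "n_total"), 0L)
  dir <- tempfile(); dir.create(dir)
  paths <- export_neuron_bundle(m, smap, p, dir)
  expect_true(all(file.exists(paths[1:3])))
  expect_equal(nrow(read_synapse_locs(paths[4])), 0)
})
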