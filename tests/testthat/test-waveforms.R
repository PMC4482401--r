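test_that("quantization truncates toward zero at 10 uV and is idempotent", {
  expect_equal(quantize(12.349999), 12.34)
  expect_equal(quantize(-80.119), -80.11)
  expect_equal(quantize(-0.005), 0)
  expect_equal(quantize(0.0199), 0.01)
  w <- c(-80.119, 12.349999, 0.004, -0.004)
  expect_equal(quantize(quantize(w)), quantize(w))
  # values sitting exactly on a boundary stay on it despite binary fp error
  expect_equal(quantize(0.29), 0.29)
  expect_equal(quantize(-70.13), -70.13)
  expect_error(quantize(c(1, NA)), "finite")
})

test_that("n_differing counts quantized sample differences", {
  w <- rep(-70.005, 100)
  expect_equal(n_differing(w, w), 0)
  z <- w; z[1:5] <- z[1:5] + 0.02
  expect_equal(n_differing(w, z), 5)
  # perturbations inside one quantization cell are invisible
  z2 <- w + 0.004   # -70.005 -> -70.001, same cell as -70.00x
  expect_equal(n_differing(w, z2), 0)
  expect_error(n_differing(w, w[-1]), "length")
})

test_that("the discriminability threshold is 'at least d points'", {
  d <- 40
  cfg <- discriminability_config(d)
  w <- rep(0.005, 200)
  z_eq <- w; z_eq[seq_len(d)] <- 0.025       # exactly d differing samples
  z_lt <- w; z_lt[seq_len(d - 1)] <- 0.025   # d - 1 differing samples
  expect_true(is_discriminable(w, z_eq, cfg))
  expect_false(is_discriminable(w, z_lt, cfg))
})

test_that("count_discriminable collapses copies and separates distinct shapes", {
  timing <- waveform_timing(dt = 1, duration = 100)
  cfg <- discriminability_config(10)
  same <- waveform_set(matrix(0.005, 6, 100), timing)
  expect_equal(count_discriminable(same, cfg)$M, 1L)

  distinct <- make_test_templates(5, 100, width = 30)
  res <- count_discriminable(waveform_set(distinct, timing), cfg)
  expect_equal(res$M, 5L)
  expect_equal(res$labels, 1:5)
})

test_that("component counting matches the BFS oracle on random sets", {
  set.seed(42)
  cfg <- discriminability_config(6)
  for (i in 1:40) {
    n <- sample(2:20, 1)
    # random template assignment with random in-cell jitter and occasional
    # boundary-crossing noise, so merges are nontrivial
    K <- sample(1:5, 1)
    tpl <- make_test_templates(K, 30, width = sample(3:20, 1))
    rows <- tpl[sample(K, n, replace = TRUE), , drop = FALSE]
    rows <- rows + matrix(runif(n * 30, 0, 0.015), n, 30)
    res <- suppressWarnings(count_discriminable(rows, cfg))
    expect_equal(res$M, oracle_component_count(rows, cfg$d))
  }
})

test_that("M is permutation invariant and non-increasing in d", {
  set.seed(7)
  tpl <- make_test_templates(4, 60, width = 25)
  rows <- tpl[sample(4, 15, replace = TRUE), ] +
    matrix(runif(15 * 60, 0, 0.012), 15, 60)
  perm <- sample(15)
  for (d in c(2, 5, 10, 26)) {
    cfg <- discriminability_config(d)
    expect_equal(suppressWarnings(count_discriminable(rows, cfg))$M,
                 suppressWarnings(count_discriminable(rows[perm, ], cfg))$M)
  }
  Ms <- vapply(c(1, 3, 6, 12, 25, 26, 61),
               function(d) suppressWarnings(
                 count_discriminable(rows, discriminability_config(d)))$M,
               integer(1))
  expect_true(all(diff(Ms) <= 0))
})

test_that("non-transitive similarity structures trigger the diagnostic warning", {
  # A close to B, B close to C, but A far from C: one component, yet the
  # A-C pair is discriminable
  n <- 30
  A <- rep(0.005, n)
  B <- A; B[1:10] <- 0.025
  C <- A; C[1:20] <- 0.025
  cfg <- discriminability_config(15)
  expect_warning(res <- count_discriminable(rbind(A, B, C), cfg),
                 "not transitive")
  expect_equal(res$M, 1L)
  expect_gt(res$non_transitive_fraction, 0)
})

test_that("template generator produces the advertised grouping structure", {
  timing <- waveform_timing(dt = 0.5, duration = 100)
  cfg <- discriminability_config(20)
  ws <- gen_waveform_templates(3, 12, separation = 50, noise_amplitude = 0.003,
                               seed = 1, timing = timing)
  expect_equal(nrow(ws), 36)
  res <- count_discriminable(ws, cfg)
  expect_equal(res$M, 3L)
  # noiseless copies are identical
  ws0 <- gen_waveform_templates(2, 4, separation = 30, noise_amplitude = 0,
                                seed = 1, timing = timing)
  expect_identical(ws0[1, ], ws0[2, ])
  # determinism
  wsA <- gen_waveform_templates(3, 5, 40, 0.002, seed = 9, timing = timing)
  wsB <- gen_waveform_templates(3, 5, 40, 0.002, seed = 9, timing = timing)
  expect_identical(unclass(wsA), unclass(wsB))
  # inconsistent parameters
  expect_error(gen_waveform_templates(2, 2, separation = 1000, timing = timing),
               "separation")
  expect_error(gen_waveform_templates(2, 2, 30, noise_amplitude = 0.02,
                                      timing = timing), "quantization")
})

test_that("waveform CSV round-trips values and timing", {
  timing <- waveform_timing(dt = 0.5, duration = 25, release_time = 5)
  ws <- waveform_set(matrix(rnorm(5 * 50, -70, 1), 5, 50), timing)
  f <- tempfile(fileext = ".csv")
  write_waveforms_csv(ws, f)
  ws2 <- read_waveforms_csv(f)
  expect_equal(unclass(ws2), unclass(ws), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(ws2, "timing")$dt, 0.5)
  expect_equal(attr(ws2, "timing")$duration, 25)
})

test_that("waveform-set construction validates dimensions", {
  expect_error(waveform_set(matrix(0, 2, 10), waveform_timing(dt = 1, duration = 100)),
               "does not match")
  expect_error(waveform_timing(dt = 0.3, duration = 100), "multiple")
})
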