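test_that("plateau search follows the cumulative-batch derivative rule", {
  # scripted repertoire growth: first batch of 10 exposes 5 shapes, the
  # second reaches 7, the third adds nothing -> derivative 2 then 0, so the
  # search runs a third round and returns the maximum (7)
  tpl <- make_test_templates(7, 50, width = 30)
  schedule <- c(rep(1:5, 2),          # calls  1-10: shapes 1..5
                rep(1:7, length.out = 10),  # calls 11-20: shapes 1..7
                rep(1:7, length.out = 10))  # calls 21-30: nothing new
  be <- make_cycling_backend(tpl, schedule = schedule)
  cfg <- estimation_config(batch_increment = 10, k_active = 3,
                           max_rounds = 50, seed = 1, d = 20)
  est <- estimate_branch_M(be, n_spines = 40, cfg)
  expect_equal(est$trace, c(5L, 7L, 7L))
  expect_equal(est$M, 7L)
  expect_equal(est$n_patterns, 30)
})

test_that("a constant backend stops after the second round with M = 1", {
  tpl <- make_test_templates(1, 50, width = 30)
  be <- make_cycling_backend(tpl)
  cfg <- estimation_config(batch_increment = 10, k_active = 2,
                           max_rounds = 50, seed = 1, d = 20)
  est <- estimate_branch_M(be, n_spines = 10, cfg)
  expect_equal(est$trace, c(1L, 1L))
  expect_equal(est$M, 1L)
})

test_that("enumerable backends are recovered exactly", {
  for (K in c(1, 3, 10)) {
    be <- make_cycling_backend(make_test_templates(K, 60, width = 25))
    cfg <- estimation_config(batch_increment = 10, k_active = 3,
                             max_rounds = 100, seed = K, d = 20)
    expect_equal(estimate_branch_M(be, n_spines = 20, cfg)$M, K)
  }
})

test_that("the estimator never exceeds the true repertoire size", {
  # pattern-hash backend: waveform determined by the pattern, repertoire K
  K <- 6L
  tpl <- make_test_templates(K, 50, width = 25)
  hash_backend <- function(patterns) {
    idx <- vapply(patterns, function(p) as.integer(sum(p)) %% K + 1L, integer(1))
    tpl[idx, , drop = FALSE]
  }
  cfg0 <- estimation_config(batch_increment = 10, k_active = 4,
                            max_rounds = 3, seed = 2, d = 20)
  for (s in 1:8) {
    cfg <- cfg0; cfg$seed <- s
    expect_lte(estimate_branch_M(hash_backend, 30, cfg)$M, K)
  }
  # and approaches it as the per-round sampling effort grows: with small
  # batches the plateau can stop early, but a 30-pattern batch rarely adds
  # nothing while shapes are still missing
  cfg_long <- estimation_config(batch_increment = 30, k_active = 4,
                                max_rounds = 100, seed = 3, d = 20)
  expect_equal(estimate_branch_M(hash_backend, 30, cfg_long)$M, K)
})

test_that("per-round traces are non-decreasing under nested pattern sets", {
  e <- list(branch_index = 1L, n_i = 15L, l_b = 30,
            positions = place_spines(30, 15, "linspace"),
            ampa = rep(TRUE, 15), nmda = rep(c(TRUE, FALSE), length.out = 15))
  be <- make_surrogate_backend(e, biophys_params(), timing = small_timing())
  cfg <- estimation_config(batch_increment = 10, k_active = 4,
                           max_rounds = 8, seed = 11, d = 10)
  est <- estimate_branch_M(be, 15, cfg)
  expect_true(all(diff(est$trace) >= 0))
})

test_that("neuron-level M sums branch estimates and handles spineless cells", {
  m <- gen_synthetic_morphology(2, 30, c(0.4, 0.8), seed = 21)
  cfg <- estimation_config(batch_increment = 10, k_active = 4,
                           max_rounds = 4, seed = 5, d = 10)
  est <- estimate_neuron_M(m, biophys_params(), cfg, timing = small_timing())
  expect_equal(est$M_total, sum(est$per_branch$M))
  expect_equal(nrow(est$per_branch), 5)
  expect_true(all(est$per_branch$M[est$per_branch$n_i == 0] == 0))

  # spineless cell: huge Cuntz constant gives zero spines, hence M = 0
  est0 <- estimate_neuron_M(m, biophys_params(), cfg, timing = small_timing(),
                            cuntz = cuntz_params(c = 1e6))
  expect_equal(est0$M_total, 0)
})

test_that("mlaw_predict applies the n log n law with the zero convention", {
  expect_equal(mlaw_predict(1, a = 3, b = 7), 7)           # ln 1 = 0
  expect_equal(mlaw_predict(c(2, 5, 9), a = 0, b = 4), 12) # 3 spiny branches * b
  expect_equal(mlaw_predict(exp(1), a = 1, b = 0), exp(1))
  expect_equal(mlaw_predict(c(0, 0, 3), a = 2, b = 5), 2 * 3 * log(3) + 5)
  expect_equal(mlaw_predict(integer(0), a = 2, b = 5), 0)
  expect_error(mlaw_predict(-1, 1, 1), ">= 0")
})

test_that("fit_mlaw recovers noiseless parameters exactly", {
  n <- c(2, 5, 10, 20, 50, 100)
  samples <- data.frame(n = n, M = 2 * n * log(n) + 5)
  fit <- fit_mlaw(samples, "nlogn")
  expect_equal(fit$a, 2, tolerance = 1e-10)
  expect_equal(fit$b, 5, tolerance = 1e-8)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-12)
})

test_that("fit_mlaw recovers noisy parameters and ranks models correctly", {
  samples <- gen_mlaw_samples(100, a = 2, b = 5, noise_sd = 0.05, seed = 1)
  fit <- fit_mlaw(samples, "nlogn")
  expect_lt(abs(fit$a - 2) / 2, 0.10)
  expect_lt(abs(fit$b - 5) / 5, 0.10)
  expect_gt(fit$adj_r2, 0.98)
  lin <- fit_mlaw(samples, "linear")
  expect_gt(fit$adj_r2, lin$adj_r2)
  quad <- fit_mlaw(samples, "quadratic")
  expect_length(quad$coefficients, 3)
})

test_that("fit/predict are mutually consistent", {
  n <- c(3, 8, 15, 40, 90)
  a <- 1.7; b <- -4
  M <- vapply(n, function(x) mlaw_predict(x, a, b), numeric(1))
  fit <- fit_mlaw(data.frame(n = n, M = M), "nlogn")
  expect_equal(fit$a, a, tolerance = 1e-9)
  expect_equal(fit$b, b, tolerance = 1e-9)
})

test_that("fit_mlaw rejects degenerate designs", {
  expect_error(fit_mlaw(data.frame(n = c(4, 4, 4), M = 1:3)), "degenerate")
  expect_error(fit_mlaw(data.frame(n = 1:2, M = 1:2)), "at least 3")
})
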