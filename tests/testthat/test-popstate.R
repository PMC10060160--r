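test_that("closed-form gain matches trivial cases and scales equivariantly", {
  f <- c(1, 2, 3, 0.5)
  expect_equal(estimate_gain(2 * f, f), 2)
  expect_equal(estimate_gain(rep(0, 4), f), 0)
  expect_error(estimate_gain(f, rep(0, 4)), "all-zero tuning")
  # exact equivariance: scaling activity by c scales the estimate by c
  r <- c(0.3, 1.1, 2.2, 0.1)
  expect_equal(estimate_gain(5 * r, f), 5 * estimate_gain(r, f))
})

test_that("closed-form gain equals the grid-search least-squares minimizer", {
  set.seed(31)
  for (trial in 1:50) {
    n <- sample(5:40, 1)
    f <- rexp(n)
    alpha <- runif(1, 0.2, 3)
    r <- alpha * f + rnorm(n, 0, 0.1)
    a_hat <- estimate_gain(r, f)
    # independent oracle: golden-ratio-free dense grid + quadratic refine
    grid <- seq(0, 5, length.out = 20001)
    sse <- vapply(grid, function(a) sum((r - a * f)^2), numeric(1))
    a_grid <- grid[which.min(sse)]
    expect_lt(abs(a_hat - a_grid), 5e-4 + 1e-6) # grid resolution 2.5e-4
  }
})

test_that("the gain estimator is unbiased under additive Gaussian noise", {
  set.seed(32)
  n <- 50
  f <- rexp(n) + 0.1
  alpha <- 1.3
  est <- replicate(10000, estimate_gain(alpha * f + rnorm(n, 0, 0.3), f))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - alpha), 3 * se)
})

test_that("gain traces recover a ground-truth step within 0.05", {
  sess <- stepped_gain_session(seed = 7, n_neurons = 80)
  rec <- sess$recording
  baseline <- sess$baseline
  sc <- score_neurons(rec, frames = baseline)
  ts <- classify_hd_cells(rec, 0.3, scores = sc)
  em <- fit_emission(rec, frames = baseline)
  dec <- decode_session(rec, em)
  gt <- gain_trace(rec, ts, dec, baseline_frames = baseline)
  fr <- rec$frame_rate
  blk <- function(a, b) mean(gt$alpha_norm[(a * fr + 5 * fr):(b * fr)],
                             na.rm = TRUE)
  expect_lt(abs(blk(180, 240) - 0.6), 0.05)
  expect_lt(abs(blk(240, 300) - 1.0), 0.05)
  # baseline mean is exactly 1 by construction
  expect_equal(mean(gt$alpha_norm[baseline], na.rm = TRUE), 1)
  # normalization idempotence
  renorm <- gt$alpha_norm / mean(gt$alpha_norm[baseline], na.rm = TRUE)
  expect_equal(renorm, gt$alpha_norm)
})

test_that("constant-gain sessions give a flat normalized trace", {
  sess <- small_session(seed = 16, n_neurons = 100, duration = 240)
  rec <- sess$recording
  sc <- score_neurons(rec)
  ts <- classify_hd_cells(rec, 0.3, scores = sc)
  em <- fit_emission(rec)
  dec <- decode_session(rec, em)
  gt <- gain_trace(rec, ts, dec,
                   baseline_frames = seq_len(ncol(rec$activity)))
  # per-frame estimates carry emission noise; 10-s block means of the
  # normalized trace must sit within 0.05 of 1 everywhere
  fr <- rec$frame_rate
  blocks <- split(gt$alpha_norm, (seq_along(gt$alpha_norm) - 1) %/% (30 * fr))
  block_means <- vapply(blocks, mean, numeric(1), na.rm = TRUE)
  expect_lt(max(abs(block_means - 1)), 0.05)
  expect_lt(median(abs(gt$alpha_norm - 1), na.rm = TRUE), 0.1)
})

test_that("bump reconstruction follows the normalized weighted-sum formula", {
  sess <- small_session(seed = 17, n_neurons = 30, duration = 200)
  rec <- sess$recording
  ts <- classify_hd_cells(rec, 0.3)
  ids <- which(ts$scores$is_hd)
  Fmat <- vapply(ts$curves[ids], function(cv) cv$rates, numeric(360))
  # single active neuron: A = c * f_1 / sum_i f_i
  r <- rep(0, nrow(rec$activity)); r[ids[1]] <- 2
  A <- reconstruct_bump(r, ts)
  expect_equal(A, 2 * Fmat[, 1] / rowSums(Fmat), tolerance = 1e-10)
  # identical flat curves: A = mean(r) everywhere
  flat_ts <- ts
  for (i in seq_along(flat_ts$curves)) flat_ts$curves[[i]]$rates <- rep(1, 360)
  r2 <- rexp(nrow(rec$activity))
  A2 <- reconstruct_bump(r2, flat_ts)
  expect_equal(A2, rep(mean(r2[ids]), 360), tolerance = 1e-10)
})

test_that("the reconstructed bump peaks at the decoded head direction", {
  # a dense population: with sparse heterogeneous tuning the weighted-sum
  # kernel itself is skewed by a few degrees, independent of noise
  cfg <- synth_config(n_neurons = 120, frac_hd = 1, duration = 120, seed = 18)
  sess <- simulate_session(cfg)
  rec <- sess$recording
  ts <- classify_hd_cells(rec, 0.3)
  em <- fit_emission(rec)
  dec <- decode_session(rec, em)
  act <- firing_activity(rec)
  errs <- vapply(seq(100, 3000, by = 200), function(t) {
    # average the bump over a short window to beat emission noise
    A <- rowMeans(reconstruct_bump(act[, (t - 5):(t + 5)], ts))
    abs(ang_diff(dec$map_hd[t], bump_centre(A)))
  }, numeric(1))
  expect_lt(median(errs), 5)
})

test_that("gain-radius correlation handles exact and degenerate relationships", {
  g <- runif(500, 0.5, 1.5)
  expect_equal(gain_radius_correlation(g, 2 * g + 1)$r_squared, 1)
  set.seed(19)
  indep <- gain_radius_correlation(g, rnorm(500))
  expect_lt(indep$r_squared, 0.05)
  expect_error(gain_radius_correlation(rep(1, 500), rnorm(500)), "constant")
})
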