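test_that("ZIG parameters are recovered from dense simulated data", {
  # constant parameters across bins, ~1e4 samples per bin after smoothing
  set.seed(12)
  n_frames <- 72000
  hd <- rep(seq(-180, 179.5, by = 0.5), length.out = n_frames)
  p0 <- 0.4; shape <- 2.5; scale <- 0.8
  draws <- ifelse(runif(n_frames) < p0, 0,
                  rgamma(n_frames, shape = shape, scale = scale))
  rec <- population_recording(matrix(draws, nrow = 1), hd)
  em <- fit_emission(rec, smooth_deg = 61)
  expect_lt(max(abs(em$p_zero[, 1] - p0)) / p0, 0.05)
  expect_lt(max(abs(em$shape[, 1] - shape)) / shape, 0.05)
  expect_lt(max(abs(em$scale[, 1] - scale)) / scale, 0.05)
  # mixture mean matches the empirical mean
  expect_equal(mean(emission_mean(em)[, 1]), mean(draws), tolerance = 0.02)
})

test_that("degenerate emission bins are clamped, not propagated", {
  hd <- rep(seq(-180, 179, by = 1), times = 20)
  # all-zero neuron: p_zero ~ 1 everywhere, gamma at floor
  rec <- population_recording(matrix(0, 1, length(hd)), hd)
  em <- fit_emission(rec)
  expect_true(all(em$p_zero[, 1] >= 0.99))
  expect_true(all(is.finite(em$shape)) && all(em$shape > 0))
  # deterministic (zero-variance) nonzero activity hits the shape ceiling
  rec2 <- population_recording(matrix(2, 1, length(hd)), hd)
  em2 <- fit_emission(rec2)
  expect_true(all(em2$shape[, 1] == max(em2$shape[, 1])))
  expect_true(all(is.finite(em2$scale)))
})

test_that("insufficient occupancy raises an informative error", {
  hd <- rep(0, 1000) # single bin visited
  rec <- population_recording(matrix(rexp(1000), 1), hd)
  expect_error(fit_emission(rec), "insufficient occupancy")
})

test_that("log-likelihood is additive over neuron subsets", {
  sess <- small_session(seed = 13, n_neurons = 12, duration = 200)
  rec <- sess$recording
  em <- fit_emission(rec)
  frames <- 1:200
  full <- loglik_matrix(rec, em, frames = frames, smooth = 1)
  a <- loglik_matrix(rec, em, frames = frames, smooth = 1, neurons = 1:5)
  b <- loglik_matrix(rec, em, frames = frames, smooth = 1, neurons = 6:12)
  expect_equal(full, a + b, tolerance = 1e-10)
  # neuron-order relabelling leaves the matrix unchanged
  perm <- loglik_matrix(rec, em, frames = frames, smooth = 1,
                        neurons = sample(1:12))
  expect_equal(full, perm, tolerance = 1e-10)
})

test_that("a smoothing window of 1 is the identity and windows sum likelihoods", {
  sess <- small_session(seed = 14, n_neurons = 8, duration = 100)
  rec <- sess$recording
  em <- fit_emission(rec)
  M1 <- loglik_matrix(rec, em, frames = 1:50, smooth = 1)
  M5 <- loglik_matrix(rec, em, frames = 1:50, smooth = 5)
  expect_equal(ncol(M5), 50)
  # interior column = centred 5-frame sum of unsmoothed columns
  expect_equal(M5[, 25], rowSums(M1[, 23:27]), tolerance = 1e-9)
  # edge columns use truncated windows
  expect_equal(M5[, 1], rowSums(M1[, 1:3]), tolerance = 1e-9)
})

test_that("decode_map takes the argmax bin centre with first-bin tie-break", {
  M <- matrix(-10, nrow = 360, ncol = 3)
  M[181, 1] <- 0        # bin centre 0 deg
  M[37, 2] <- 0         # bin centre -144 deg
  dec <- decode_map(M)  # column 3 is flat -> first bin (-180)
  expect_equal(dec$map_hd, c(0, -144, -180))
  M[, 2] <- -Inf
  expect_error(decode_map(M), "-Inf")
})

test_that("decoding error grows as the zero-inflation probability rises", {
  maes <- vapply(c(0.3, 0.6, 0.9, 0.97), function(p0) {
    sess <- simulate_session(synth_config(
      n_neurons = 40, duration = 120, seed = 21,
      zig_params = list(p_zero = p0, shape = 2)
    ))
    rec <- sess$recording
    T <- ncol(rec$activity)
    train <- 1:round(0.8 * T)
    test <- (round(0.8 * T) + 1):T
    em <- fit_emission(rec, frames = train)
    dec <- decode_session(rec, em, frames = test)
    decode_mae(dec$map_hd, rec$measured_hd[test])
  }, numeric(1))
  expect_true(all(diff(maes) > -0.5)) # non-decreasing up to noise
  expect_gt(maes[4], maes[1])
})

test_that("held-out decoding on a small synthetic baseline is accurate", {
  sess <- small_session(seed = 3, n_neurons = 60, duration = 240)
  rec <- sess$recording
  T <- ncol(rec$activity)
  train <- 1:round(0.8 * T)
  test <- (round(0.8 * T) + 1):T
  em <- fit_emission(rec, frames = train)
  dec <- decode_session(rec, em, frames = test)
  expect_lt(decode_mae(dec$map_hd, rec$measured_hd[test]), 5.96)
})
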