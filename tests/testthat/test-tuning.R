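test_that("stimulus signal evaluates the Gaussian kernel in closed form", {
  expect_equal(stimulus_signal(120, 120), 1)
  expect_equal(stimulus_signal(120 + 17, 120), exp(-1 / 2))
  expect_equal(stimulus_signal(120 + 180, 120), exp(-180^2 / (2 * 17^2)))
  # wrap-aware: 10 degrees across the seam
  expect_equal(stimulus_signal(-175, 175), exp(-10^2 / (2 * 17^2)))
  expect_error(stimulus_signal(0, 0, sigma = 0), "sigma")
  s <- stimulus_signal(seq(-180, 179), 37)
  expect_true(all(s > 0 & s <= 1))
  expect_equal(which.max(s), 37 + 181)
})

test_that("tuning curves recover a known preferred direction", {
  sess <- small_session(seed = 4, n_neurons = 40, duration = 600)
  rec <- sess$recording
  hd_ids <- which(sess$truth$true_is_hd)
  errs <- vapply(hd_ids, function(i) {
    tc <- compute_tuning_curve(rec, i)
    abs(ang_diff(sess$truth$true_pfd[i], tc$pfd))
  }, numeric(1))
  expect_lt(median(errs), 2)
  expect_lt(max(errs), 8)
})

test_that("degenerate tuning inputs behave as documented", {
  # activity only when hd is in the bin centred at 0 -> pfd 0
  hd <- rep(seq(-180, 179, by = 1), times = 4)
  act <- matrix(0, nrow = 1, ncol = length(hd))
  act[1, wrap_angle(round(hd)) == 0] <- 1
  rec <- population_recording(act, hd, frame_rate = 30)
  tc <- compute_tuning_curve(rec, 1, activity = rec$activity)
  expect_equal(tc$pfd, 0)
  # constant activity, uniform occupancy -> flat curve, first-bin tie-break
  rec2 <- population_recording(matrix(1, 1, length(hd)), hd)
  tc2 <- compute_tuning_curve(rec2, 1, activity = rec2$activity)
  expect_equal(diff(range(tc2$rates)), 0, tolerance = 1e-9)
  expect_equal(tc2$pfd, -180)
  expect_error(compute_tuning_curve(rec, 1, frames = integer(0)), "empty")
})

test_that("hd scores are 1 for stimulus-shaped activity, negative for anti-tuned", {
  hd <- wrap_angle(cumsum(rnorm(3000, 0, 3)))
  stim <- stimulus_signal(hd, 45)
  rec <- population_recording(rbind(stim, 1 - stim, rep(0.5, length(hd))), hd)
  expect_equal(hd_score(rec, 1, 45, activity = rec$activity), 1)
  expect_lt(hd_score(rec, 2, 45, activity = rec$activity), 0)
  # zero-variance activity is defined as r = 0
  expect_equal(hd_score(rec, 3, 45, activity = rec$activity), 0)
})

test_that("white-noise activity scores near zero", {
  set.seed(5)
  hd <- wrap_angle(cumsum(rnorm(1e4, 0, 3)))
  act <- matrix(abs(rnorm(1e4)), nrow = 1)
  rec <- population_recording(act, hd)
  r <- hd_score(rec, 1, 0, activity = rec$activity)
  expect_lt(abs(r), 0.05)
})

test_that("circular shifts preserve the activity marginal (null validity)", {
  # the shuffled null draws correlations of circularly rolled copies; rolling
  # must leave the sorted values untouched
  x <- rexp(500)
  shift <- 123
  rolled <- c(x[(shift + 1):500], x[1:shift])
  expect_identical(sort(rolled), sort(x))
})

test_that("shuffle threshold converges near the null 95th percentile on pure noise", {
  set.seed(8)
  hd <- wrap_angle(cumsum(rnorm(6000, 0, 3)))
  act <- matrix(abs(rnorm(20 * 6000)), nrow = 20)
  rec <- population_recording(act, hd)
  sc <- score_neurons(rec)
  # force some neurons above the start threshold so the loop engages
  thr <- shuffle_threshold(rec, scores = list(sc), start_r = 0.2,
                           n_shuffles = 100, seed = 2)
  expect_lt(thr$r_thresh, 0.1)
  expect_lt(abs(thr$r_thresh - thr$null_quantile), 0.011)
  expect_error(shuffle_threshold(rec, n_shuffles = 0), "n_shuffles")
})

test_that("classification is monotone in the threshold and matches ground truth", {
  sess <- small_session(seed = 6, n_neurons = 50, duration = 600)
  rec <- sess$recording
  sc <- score_neurons(rec)
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7),
                   function(th) classify_hd_cells(rec, th, scores = sc)$n_hd,
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  # all-above threshold -> zero HD cells without error
  none <- classify_hd_cells(rec, 1.01, scores = sc)
  expect_equal(none$n_hd, 0)
  # shuffle-calibrated threshold recovers the configured HD fraction
  thr <- shuffle_threshold(rec, scores = list(sc), n_shuffles = 100, seed = 3)
  ts <- classify_hd_cells(rec, thr$r_thresh, scores = sc)
  expect_lt(abs(ts$frac_hd - 0.9), 0.1)
  truth <- sess$truth$true_is_hd
  bal <- 0.5 * (sum(ts$scores$is_hd & truth) / sum(truth) +
                  sum(!ts$scores$is_hd & !truth) / sum(!truth))
  expect_gte(bal, 0.95)
})
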