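test_that("offset traces follow the measured-minus-decoded sign convention", {
  hd <- wrap_angle(cumsum(rnorm(2000, 0, 2)))
  ot <- compute_offset(hd, hd, smooth = 1)
  expect_equal(ot$offset, rep(0, 2000))
  ot90 <- compute_offset(hd, wrap_angle(hd - 90), smooth = 1)
  expect_equal(ot90$offset, rep(90, 2000))
  # hand wrap case
  ot2 <- compute_offset(175, -175, smooth = 1)
  expect_equal(ot2$offset, -10)
})

test_that("drift speed matches ramps, constants and windowed regression", {
  fr <- 30
  ramp <- wrap_angle(seq(0, 600, by = 1)) # 1 deg/frame = 30 deg/s
  ds <- drift_speed(ramp, window = 20, frame_rate = fr)
  interior <- ds[30:570]
  expect_equal(interior, rep(30, length(interior)), tolerance = 1e-9)
  expect_equal(drift_speed(rep(42, 100), 20, fr)[50], 0)
  expect_error(drift_speed(rep(0, 10), window = 20), "window")
  # matches lm() slope exactly on an interior window
  set.seed(41)
  x <- cumsum(rnorm(200, 0, 0.5))
  ds2 <- drift_speed(wrap_angle(x), window = 20, frame_rate = fr)
  i <- 100
  idx <- (i - 10):(i + 9)
  expect_equal(ds2[i], unname(coef(lm(x[idx] ~ idx))[2]) * fr,
               tolerance = 1e-8)
  # quadratic: sliding slope equals the analytic derivative up to O(w^2) bias
  q <- 0.001 * (1:400)^2
  dq <- drift_speed(wrap_angle(q), window = 20, frame_rate = 1)
  expect_equal(dq[200], 0.002 * 200, tolerance = 0.03)
})

test_that("unwrap correctness: wrap jumps produce no drift-speed spikes", {
  # offset crossing the seam smoothly at 30 deg/s
  off <- wrap_angle(seq(150, 250, by = 1))
  ds <- drift_speed(off, window = 20, frame_rate = 30)
  expect_equal(max(abs(ds[20:80] - 30)), 0, tolerance = 1e-9)
})

test_that("reset events capture onset, stabilization and range", {
  fr <- 30
  # baseline 60 s, darkness 60 s, cue 120 s with an instantaneous 90 shift
  epochs <- data.frame(label = c("baseline", "D1", "C1"),
                       start = c(1, 1801, 3601), end = c(1800, 3600, 7200))
  off <- c(rep(0, 3600), rep(90, 3600)) + rnorm(7200, 0, 1)
  ev <- extract_reset_events(wrap_angle(off), epochs, frame_rate = fr,
                             traj_frames = 600)
  expect_equal(nrow(ev$events), 1)
  expect_true(ev$events$included)
  expect_gt(ev$events$reset_range, 70)
  expect_lt(ev$events$reset_range, 110)
  # trajectory is onset-referenced
  expect_lt(abs(ev$trajectories[1, 1]), 5)
  # no change in offset -> range about 0
  ev0 <- extract_reset_events(rep(5, 7200), epochs, frame_rate = fr,
                              traj_frames = 600)
  expect_lt(ev0$events$reset_range, 1)
  # too-short cue epochs are flagged and excluded
  short_ep <- data.frame(label = c("baseline", "C1"),
                         start = c(1, 1801), end = c(1800, 2100))
  evs <- extract_reset_events(rep(0, 2100), short_ep, frame_rate = fr)
  expect_false(evs$events$included)
})

test_that("known reset ranges are recovered and grouped", {
  fr <- 30
  ranges <- c(30, 90, 150)
  epochs <- data.frame(
    label = c("baseline", "D1", "C1", "D2", "C2", "D3", "C3"),
    start = c(1, 1801, 3601, 7201, 9001, 12601, 14401),
    end = c(1800, 3600, 7200, 9000, 12600, 14400, 18000)
  )
  off <- numeric(18000)
  off[3601:7200] <- 30
  off[7201:9000] <- 30
  off[9001:12600] <- 30 + 90
  off[12601:14400] <- 120
  off[14401:18000] <- 120 + 150
  ev <- extract_reset_events(wrap_angle(off), epochs, frame_rate = fr,
                             traj_frames = 600)
  expect_equal(ev$events$reset_range, ranges, tolerance = 1)
  grp <- filter_reset_range(ev, c(70, 110))
  expect_equal(grp$events$label, "C2")
})

test_that("k-means with city-block metric separates fast and slow resets", {
  fast <- make_reset_family(8, tau_s = 2, seed = 51)
  slow <- make_reset_family(7, tau_s = 60, seed = 52)
  X <- rbind(fast, slow)
  cl <- classify_fast_slow(X, seed = 9)
  expect_equal(as.character(cl$labels),
               c(rep("fast", 8), rep("slow", 7)))
  # deterministic under the seed
  cl2 <- classify_fast_slow(X, seed = 9)
  expect_identical(cl$labels, cl2$labels)
  # invariant to row permutation
  set.seed(1)
  perm <- sample(nrow(X))
  cl3 <- classify_fast_slow(X[perm, ], seed = 9)
  expect_identical(as.character(cl3$labels),
                   as.character(cl$labels[perm]))
  expect_error(classify_fast_slow(X[1, , drop = FALSE]), "at least")
  expect_error(classify_fast_slow(rbind(X[1, ], X[1, ])), "identical")
})

test_that("darkness drift dispersion grows under injected OU drift", {
  set.seed(53)
  fr <- 30
  ou <- function(n, sd, tau) {
    rho <- exp(-1 / (fr * tau))
    x <- numeric(n)
    for (t in 2:n) x[t] <- rho * x[t - 1] + rnorm(1, 0, sd * sqrt(1 - rho^2))
    x
  }
  traces <- c(
    lapply(1:6, function(i) rnorm(3600, 0, 1)),          # baseline-like
    lapply(1:6, function(i) ou(3600, 40, 60))            # darkness drift
  )
  groups <- rep(c("baseline", "darkness"), each = 6)
  st <- darkness_drift_stats(traces, groups)
  disp <- split(st$epoch_dispersion, groups)
  expect_gt(mean(disp$darkness), mean(disp$baseline))
  expect_lt(st$test$p.value, 0.05)
  # constant trace has zero dispersion
  st0 <- darkness_drift_stats(list(rep(25, 100)))
  expect_equal(unname(st0$epoch_dispersion[1]), 0, tolerance = 1e-6)
})

test_that("clockwise reflection is an involution and flips signs", {
  sess <- small_session(seed = 54, n_neurons = 10, duration = 20)
  rec <- sess$recording
  twice <- reflect_clockwise(reflect_clockwise(rec))
  expect_equal(twice$measured_hd, rec$measured_hd)
  expect_equal(twice$cue_angle, rec$cue_angle)
  refl <- reflect_clockwise(rec)
  ok <- rec$measured_hd != -180
  expect_equal(refl$measured_hd[ok], -rec$measured_hd[ok])
  # drift-speed sign flips, magnitude preserved
  ot <- compute_offset(rec$measured_hd, wrap_angle(rec$measured_hd - 30))
  rt <- reflect_clockwise(ot)
  expect_equal(rt$drift_speed, -ot$drift_speed)
})

test_that("cue-rotation inclusion windows match the stated ranges", {
  expect_true(filter_rotation_sessions(160, "fast"))
  expect_false(filter_rotation_sessions(100, "fast"))
  expect_true(filter_rotation_sessions(-90, "slow"))
  expect_true(filter_rotation_sessions(-150, "fast"))
  expect_false(filter_rotation_sessions(-150, "slow"))
  expect_equal(filter_rotation_sessions(c(170, -60), c("fast", "slow")),
               c(TRUE, TRUE))
})
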