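test_that("trajectories are deterministic, wrapped, and cover the circle", {
  cfg <- synth_config(duration = 600, seed = 42)
  hd1 <- simulate_trajectory(cfg)
  hd2 <- simulate_trajectory(cfg)
  expect_identical(hd1, hd2)
  expect_true(all(hd1 >= -180 & hd1 < 180))
  # occupancy histogram oracle: every 1-degree bin visited at 600 s
  occ <- tabulate(as.integer(wrap_angle(round(hd1))) + 181L, nbins = 360)
  expect_true(all(occ > 0))
})

test_that("zero-velocity-noise trajectories are constant", {
  cfg <- synth_config(duration = 10, traj_speed_sd = 0, seed = 1)
  hd <- simulate_trajectory(cfg)
  expect_equal(hd, rep(hd[1], length(hd)))
  expect_error(synth_config(duration = -5), "duration")
})

test_that("two-minute-shift protocol steps the cue by 90 degrees per event", {
  cfg <- synth_config(protocol = "two_min_shift", seed = 1)
  proto <- build_protocol(cfg)
  labels <- proto$epochs$label
  expect_equal(labels, c("baseline", "D1", "C1", "D2", "C2", "D3", "C3",
                         "D4", "C4"))
  cue_at <- function(lab) {
    ep <- proto$epochs[proto$epochs$label == lab, ]
    unique(proto$cue_angle[ep$start:ep$end])
  }
  expect_equal(cue_at("baseline"), 0)
  expect_equal(cue_at("C1"), 90)
  expect_equal(cue_at("C2"), -180)   # wrapped +180
  expect_equal(cue_at("C3"), -90)    # wrapped +270
  expect_equal(cue_at("C4"), 0)      # wrapped +360
  # darkness frames carry the cue-off sentinel
  d1 <- proto$epochs[proto$epochs$label == "D1", ]
  expect_true(all(is.nan(proto$cue_angle[d1$start:d1$end])))
})

test_that("cue rotation at 3 deg/s for 7 min ends 180 degrees away", {
  cfg <- synth_config(protocol = "cue_rotation", rotation_speed = 3.0,
                      seed = 1)
  proto <- build_protocol(cfg)
  rot <- proto$epochs[proto$epochs$label == "rotation", ]
  final <- proto$cue_angle[rot$end]
  # 3 deg/s * 420 s = 1260 = 180 (mod 360)
  expect_equal(abs(final), 180, tolerance = 0.2)
  # schedules are pure functions of the config
  expect_identical(proto, build_protocol(cfg))
})

test_that("twenty-second-shift protocol alternates +-90 flashes between darkness", {
  cfg <- synth_config(protocol = "twenty_s_shift", seed = 1)
  proto <- build_protocol(cfg)
  d_epochs <- grep("^D", proto$epochs$label, value = TRUE)
  expect_gte(length(d_epochs), 5)
  c_eps <- proto$epochs[startsWith(proto$epochs$label, "C"), ]
  cues <- vapply(seq_len(nrow(c_eps)), function(i)
    proto$cue_angle[c_eps$start[i]], numeric(1))
  expect_equal(cues, c(90, -90, 90, -90, 90, -90))
  expect_equal(unique(c_eps$end - c_eps$start + 1L), 20 * cfg$frame_rate)
})

test_that("population emission matches the gain-scaled tuning in the noiseless limit", {
  cfg <- synth_config(n_neurons = 20, duration = 10, noise = "none", seed = 2)
  hd <- simulate_trajectory(cfg)
  gain <- seq(0.5, 1.5, length.out = length(hd))
  out <- generate_population(cfg, hd, true_gain = gain)
  tr <- out$truth
  i <- which(tr$true_is_hd)[1]
  f_i <- tr$true_peak[i] *
    exp(tr$true_kappa[i] * (cos((hd - tr$true_pfd[i]) * pi / 180) - 1))
  expect_equal(out$recording$activity[i, ], gain * f_i, tolerance = 1e-12)
  # non-HD neuron mean is direction-independent
  j <- which(!tr$true_is_hd)[1]
  expect_equal(out$recording$activity[j, ] / gain,
               rep(tr$baseline_rate[j], length(hd)), tolerance = 1e-12)
})

test_that("p_zero = 1 yields an all-zero activity matrix and negative gain errors", {
  cfg <- synth_config(n_neurons = 10, duration = 5, seed = 1,
                      zig_params = list(p_zero = 1, shape = 2))
  hd <- simulate_trajectory(cfg)
  out <- generate_population(cfg, hd)
  expect_true(all(out$recording$activity == 0))
  expect_error(generate_population(cfg, hd, true_gain = rep(-1, length(hd))),
               "true_gain")
})

test_that("binned conditional means recover the gain-weighted tuning curves", {
  # Monte-Carlo oracle: with constant gain alpha, E[activity | hd bin] should
  # match alpha * f_i(bin centre) within 3 standard errors
  cfg <- synth_config(n_neurons = 6, frac_hd = 1, duration = 3600,
                      frame_rate = 30, seed = 9)
  n <- 108000
  hd <- wrap_angle(runif(n, -180, 180))
  alpha <- 0.8
  out <- generate_population(cfg, hd, true_gain = rep(alpha, n))
  tr <- out$truth
  i <- 3
  bins <- as.integer(wrap_angle(round(hd))) + 181L
  act <- out$recording$activity[i, ]
  for (b in c(1, 90, 181, 270)) {
    sel <- bins == b
    mu_hat <- mean(act[sel])
    se <- sd(act[sel]) / sqrt(sum(sel))
    centre <- b - 181
    mu_true <- alpha * tr$true_peak[i] *
      exp(tr$true_kappa[i] * (cos((centre - tr$true_pfd[i]) * pi / 180) - 1))
    expect_lt(abs(mu_hat - mu_true), 3 * se + 1e-6)
  }
})

test_that("sessions are reproducible bit for bit under a fixed seed", {
  a <- small_session(seed = 11, n_neurons = 15, duration = 20)
  b <- small_session(seed = 11, n_neurons = 15, duration = 20)
  expect_identical(a$recording$activity, b$recording$activity)
  expect_identical(a$truth, b$truth)
})

test_that("recording invariants are enforced", {
  expect_error(population_recording(matrix(-1, 2, 3), c(0, 0, 0)),
               "non-negative")
  expect_error(population_recording(matrix(1, 2, 3), c(0, 0)), "length")
  bad_epochs <- data.frame(label = c("a", "b"), start = c(1, 2), end = c(2, 3))
  expect_error(population_recording(matrix(1, 2, 3), c(0, 0, 0),
                                    epochs = bad_epochs), "disjoint")
})
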