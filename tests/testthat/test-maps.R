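test_that("gain tuning curves recover a cosine gain landscape", {
  set.seed(61)
  n <- 60000
  ihd <- wrap_angle(runif(n, -180, 180))
  gain <- 1 + 0.3 * cos(ihd * pi / 180) + rnorm(n, 0, 0.05)
  gc <- gain_tuning_curve(gain, ihd)
  peak_at <- hd_bin_centres()[which.max(gc$curve)]
  expect_lt(abs(ang_diff(0, peak_at)), 10)
  amp <- (max(gc$curve) - min(gc$curve)) / 2
  expect_lt(abs(amp - 0.3), 0.05)
  # constant gain -> flat curve
  flat <- gain_tuning_curve(rep(1.2, n), ihd)
  expect_lt(diff(range(flat$curve)), 1e-6)
})

test_that("heat maps of a constant signal are constant on visited pixels", {
  set.seed(62)
  n <- 20000
  vel <- rnorm(n, 0, 30)
  ihd <- wrap_angle(runif(n, -180, 180))
  hm <- build_heatmap(rep(2.5, n), vel, ihd, gauss_sd = 3)
  visited <- !is.na(hm$values)
  expect_true(any(visited))
  expect_equal(unique(round(hm$values[visited], 9)), 2.5)
  # raw window means equal plain binned means when the window is zero-width
  hm0 <- build_heatmap(rep(2.5, n), vel, ihd, v_win = 0, hd_win = 0,
                       gauss_sd = 0)
  expect_equal(unique(round(hm0$values[!is.na(hm0$values)], 9)), 2.5)
})

test_that("an injected gain hotspot survives windowing and blurring", {
  set.seed(63)
  n <- 60000
  vel <- runif(n, -60, 60)
  ihd <- wrap_angle(runif(n, -180, 180))
  sig <- rep(1, n)
  hot <- abs(vel - 30) < 5 & abs(ang_diff(0, ihd)) < 10
  sig[hot] <- 3
  hm <- build_heatmap(sig, vel, ihd, v_range = c(-60, 60), gauss_sd = 5)
  pk <- which(hm$values == max(hm$values, na.rm = TRUE), arr.ind = TRUE)
  expect_lt(abs(hm$v_centres[pk[1]] - 30), 8)
  expect_lt(abs(ang_diff(0, hm$hd_centres[pk[2]])), 20)
})

test_that("the HD axis of the blur has no seam at +-180", {
  set.seed(64)
  n <- 60000
  vel <- runif(n, -30, 30)
  ihd <- wrap_angle(runif(n, -180, 180))
  # signal smooth across the seam: cos(ihd - 180)
  sig <- cos((ihd - 180) * pi / 180)
  hm <- build_heatmap(sig, vel, ihd, v_range = c(-30, 30), gauss_sd = 10)
  row <- hm$values[10, ]
  # values at bins adjacent across the seam are close
  expect_lt(abs(row[1] - row[360]), 0.05)
  # and the maximum sits near the seam, not suppressed by it
  expect_gt(max(row[c(1:20, 341:360)]), max(row[160:200]))
})

test_that("heat-map comparison masks by significance and sign", {
  set.seed(65)
  n <- 30000
  vel <- runif(n, -30, 30)
  ihd <- wrap_angle(runif(n, -180, 180))
  sa <- list(signal = rnorm(n, 1.5, 0.2), velocity = vel, internal_hd = ihd)
  sb <- list(signal = rnorm(n, 1.0, 0.2), velocity = vel, internal_hd = ihd)
  args <- list(v_range = c(-30, 30), v_bin = 10, v_win = 10, hd_win = 45,
               gauss_sd = 0)
  hma <- do.call(build_heatmap, c(list(sa$signal, vel, ihd), args))
  hmb <- do.call(build_heatmap, c(list(sb$signal, vel, ihd), args))
  cmp <- compare_heatmaps(hma, hmb, sa, sb)
  filled <- !is.na(cmp$p_matrix)
  expect_true(all(cmp$p_matrix[filled] < 0.001))
  expect_equal(mean(cmp$difference[filled]), 0.5, tolerance = 0.05)
  # identical sample sets: everything masked
  cmp0 <- compare_heatmaps(hma, hma, sa, sa)
  expect_true(all(is.nan(cmp0$difference[filled])))
  # positive_only off keeps significant negative differences
  cmp_neg <- compare_heatmaps(hmb, hma, sb, sa, positive_only = FALSE)
  expect_lt(mean(cmp_neg$difference[!is.nan(cmp_neg$difference)]), 0)
  cmp_pos <- compare_heatmaps(hmb, hma, sb, sa, positive_only = TRUE)
  expect_true(all(is.nan(cmp_pos$difference[filled])))
  # binning mismatch errors
  hmc <- build_heatmap(sa$signal, vel, ihd, v_range = c(-30, 30), v_bin = 15)
  expect_error(compare_heatmaps(hma, hmc, sa, sa), "mismatch")
})

test_that("a darkness gain landscape peaked at the cue yields a centred map", {
  # end-to-end memory-trace property: tuning and emission models come from a
  # flat-gain baseline half; the second half carries a gain landscape peaked
  # at the (remembered) cue location 0, which the recovered gain tuning curve
  # must re-centre on
  cfg <- synth_config(n_neurons = 80, duration = 480, seed = 66)
  proto <- build_protocol(cfg)
  hd <- simulate_trajectory(cfg, proto$n_frames)
  nf <- proto$n_frames
  baseline <- seq_len(nf / 2)
  dark <- (nf / 2 + 1):nf
  gain <- rep(1, nf)
  gain[dark] <- 1 + 0.25 * cos(hd[dark] * pi / 180) # internal = measured here
  sess <- generate_population(cfg, hd, true_gain = gain)
  rec <- sess$recording
  ts <- classify_hd_cells(rec, 0.3, frames = baseline)
  em <- fit_emission(rec, frames = baseline)
  dec <- decode_session(rec, em)
  gt <- gain_trace(rec, ts, dec, baseline_frames = baseline)
  gc <- gain_tuning_curve(gt$alpha_norm[dark], dec$map_hd[dark])
  com <- bump_centre(gc$curve - min(gc$curve))
  expect_lt(abs(ang_diff(0, com)), 10)
  peak <- hd_bin_centres()[which.max(gc$curve)]
  expect_lt(abs(ang_diff(0, peak)), 15)
  # the baseline half stays flat
  gcb <- gain_tuning_curve(gt$alpha_norm[baseline], dec$map_hd[baseline])
  expect_lt(diff(range(gcb$curve)), 0.15)
})
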