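# Synthetic head-direction sessions with known ground truth.
#
# The generator emulates the statistics of miniscope recordings from the
# anterodorsal thalamus: von Mises HD tuning tiling 360 degrees,
# zero-inflated-gamma (ZIG) deconvolved activity, a global multiplicative
# gain, smooth head trajectories on a circular platform, and the three cue
# protocols (2-min 90-degree shifts with darkness, 20-s alternating +-90
# flashes, continuous cue rotation at 1.5 or 3.0 deg/s).

#' Sentinel marking frames with no visual cue
#'
#' The cue-angle channel carries `CUE_OFF` (`NaN`) on every frame inside a
#' darkness epoch; epoch labels are authoritative.
#' @export
CUE_OFF <- NaN

# deterministic per-stage substream from one master seed (kept below 2^31)
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 10007 + h) %% 2147483647)
}

#' Configuration for a synthetic session
#'
#' Defaults describe a typical recording: ~165 simultaneously imaged ADN
#' cells of which ~90% are HD-tuned, 30 Hz imaging, concentration of the von
#' Mises tuning curves drawn per neuron from `kappa_range` (half-width at
#' half-maximum roughly 25-40 degrees), and ZIG emission noise. Tuning-width
#' and peak-rate distributions are assumptions of the generator (no
#' published parametric values exist); see the package vignette.
#'
#' @param n_neurons number of simultaneously recorded cells.
#' @param frac_hd fraction of HD-tuned cells in `[0, 1]`.
#' @param frame_rate imaging rate, Hz.
#' @param duration session length in seconds (used directly for the
#'   `baseline_only` protocol; the cue protocols fix their own schedule).
#' @param kappa_range interval for per-neuron von Mises concentration.
#' @param peak_rate_range interval for per-neuron peak activity (a.u.).
#' @param zig_params list with `p_zero` (probability of an exact zero) and
#'   `shape` (gamma shape); the gamma scale is set per frame so the ZIG mean
#'   matches the tuning-predicted rate.
#' @param traj_speed_sd stationary s.d. of head angular velocity, deg/s.
#' @param traj_tau autocorrelation time constant of angular velocity, s.
#' @param gain_profile per-frame multiplicative gain (>= 0), or `NULL` for
#'   constant 1.
#' @param protocol one of `"baseline_only"`, `"two_min_shift"`,
#'   `"twenty_s_shift"`, `"cue_rotation"`.
#' @param rotation_speed cue rotation speed, deg/s (1.5 or 3.0).
#' @param shift_dir +1 for counter-clockwise cue shifts/rotation, -1 for
#'   clockwise.
#' @param drift_sd stationary s.d. (deg) of the Ornstein-Uhlenbeck internal
#'   drift injected during darkness.
#' @param drift_tau OU time constant of the darkness drift, s.
#' @param reset_tau time constant (s) of the exponential relaxation of the
#'   internal offset toward the cue-implied value after cue onset.
#' @param noise `"zig"` for stochastic emission, `"none"` for the noiseless
#'   limit (activity equals its conditional mean).
#' @param seed master integer seed; every random stage derives a named
#'   substream from it.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_neurons = 165,
                         frac_hd = 0.9,
                         frame_rate = 30,
                         duration = 600,
                         kappa_range = c(3, 8),
                         peak_rate_range = c(0.5, 2),
                         zig_params = list(p_zero = 0.5, shape = 2),
                         traj_speed_sd = 60,
                         traj_tau = 0.5,
                         gain_profile = NULL,
                         protocol = c("baseline_only", "two_min_shift",
                                      "twenty_s_shift", "cue_rotation"),
                         rotation_speed = 3.0,
                         shift_dir = 1,
                         drift_sd = 25,
                         drift_tau = 60,
                         reset_tau = 5,
                         noise = c("zig", "none"),
                         seed = 1L) {
  protocol <- match.arg(protocol)
  noise <- match.arg(noise)
  if (duration <= 0) stop("invalid config: duration must be > 0")
  if (frame_rate <= 0) stop("invalid config: frame_rate must be > 0")
  if (frac_hd < 0 || frac_hd > 1) stop("invalid config: frac_hd must be in [0, 1]")
  if (!is.null(gain_profile) && any(gain_profile < 0))
    stop("invalid config: gain_profile must be >= 0")
  if (!(zig_params$p_zero >= 0 && zig_params$p_zero <= 1))
    stop("invalid config: zig p_zero must be in [0, 1]")
  if (zig_params$shape <= 0) stop("invalid config: zig shape must be > 0")
  structure(
    list(
      n_neurons = as.integer(n_neurons), frac_hd = frac_hd,
      frame_rate = frame_rate, duration = duration,
      kappa_range = kappa_range, peak_rate_range = peak_rate_range,
      zig_params = zig_params, traj_speed_sd = traj_speed_sd,
      traj_tau = traj_tau, gain_profile = gain_profile,
      protocol = protocol, rotation_speed = rotation_speed,
      shift_dir = shift_dir, drift_sd = drift_sd, drift_tau = drift_tau,
      reset_tau = reset_tau, noise = noise, seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Read a synthetic-session configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [synth_config()].
#' @return a `synth_config` object.
#' @export
read_synth_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(synth_config, vals)
}

#' Simulate a smooth head trajectory
#'
#' Angular velocity follows a discretized Ornstein-Uhlenbeck process
#' (autocorrelated, bounded random walk) with stationary standard deviation
#' `traj_speed_sd`; heading is its wrapped integral. Emulates free
#' exploration on an elevated circular platform. For sessions of at least
#' 180 s the generator guarantees that every 1-degree bin is visited,
#' re-drawing the trajectory (bounded number of attempts) if coverage fails.
#'
#' @param config a [synth_config()].
#' @param n_frames optional frame count override (defaults to
#'   `duration * frame_rate`).
#' @return numeric vector of headings in `[-180, 180)` degrees.
#' @export
simulate_trajectory <- function(config, n_frames = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(n_frames)) n_frames <- round(config$duration * config$frame_rate)
  n_frames <- as.integer(n_frames)
  if (n_frames <= 0) stop("invalid-config: non-positive duration")
  dt <- 1 / config$frame_rate
  rho <- exp(-dt / config$traj_tau)
  sd_innov <- config$traj_speed_sd * sqrt(1 - rho^2)
  want_cover <- (n_frames * dt) >= 180 && config$traj_speed_sd > 0
  for (attempt in 1:25) {
    set.seed(substream_seed(config$seed, paste0("traj", attempt)))
    v <- numeric(n_frames)
    if (config$traj_speed_sd > 0) {
      v[1] <- stats::rnorm(1, 0, config$traj_speed_sd)
      innov <- stats::rnorm(n_frames - 1L, 0, sd_innov)
      for (t in 2:n_frames) v[t] <- rho * v[t - 1L] + innov[t - 1L]
    }
    hd <- wrap_angle(cumsum(v * dt))
    if (!want_cover) return(hd)
    if (length(unique(hd_bin_index(hd))) == 360L) return(hd)
  }
  stop("trajectory failed to cover all 360 bins after 25 attempts")
}

#' Build the epoch schedule and cue-angle series for a protocol
#'
#' Pure function of the configuration. Schedules:
#' \describe{
#'   \item{baseline_only}{single epoch of `duration` s, cue fixed at 0.}
#'   \item{two_min_shift}{3-min baseline, then four repeats of (2-min
#'     darkness, 2-min cue displayed 90 degrees beyond its previous
#'     position, direction `shift_dir`).}
#'   \item{twenty_s_shift}{3-min baseline, then six repeats of (2-min
#'     darkness, 20-s cue flash alternating at +90/-90 from baseline),
#'     closed by a final darkness epoch (D1..D7).}
#'   \item{cue_rotation}{3-min baseline at 0, 2-min darkness, 7-min
#'     continuous rotation at `rotation_speed * shift_dir` starting from the
#'     baseline position, 2-min darkness.}
#' }
#'
#' @param config a [synth_config()].
#' @return list with `epochs` (data.frame: `label`, `start`, `end`, 1-based
#'   inclusive frames), `cue_angle` (deg, `CUE_OFF` in darkness) and
#'   `n_frames`.
#' @export
build_protocol <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  fr <- config$frame_rate
  fl <- function(sec) as.integer(round(sec * fr))
  segs <- list() # list of (label, n_frames, cue value(s))
  add <- function(label, nfr, cue) segs[[length(segs) + 1L]] <<- list(label, nfr, cue)
  switch(config$protocol,
    baseline_only = {
      add("baseline", fl(config$duration), 0)
    },
    two_min_shift = {
      add("baseline", fl(180), 0)
      pos <- 0
      for (k in 1:4) {
        add(paste0("D", k), fl(120), CUE_OFF)
        pos <- pos + 90 * config$shift_dir
        add(paste0("C", k), fl(120), wrap_angle(pos))
      }
    },
    twenty_s_shift = {
      add("baseline", fl(180), 0)
      for (k in 1:6) {
        add(paste0("D", k), fl(120), CUE_OFF)
        add(paste0("C", k), fl(20), wrap_angle(90 * config$shift_dir * (-1)^(k - 1)))
      }
      add("D7", fl(120), CUE_OFF)
    },
    cue_rotation = {
      add("baseline", fl(180), 0)
      add("D1", fl(120), CUE_OFF)
      nrot <- fl(420)
      rot <- wrap_angle(config$rotation_speed * config$shift_dir *
                          (seq_len(nrot) - 1L) / fr)
      add("rotation", nrot, rot)
      add("D2", fl(120), CUE_OFF)
    },
    stop("unknown protocol: ", config$protocol)
  )
  labels <- vapply(segs, `[[`, "", 1L)
  lens <- vapply(segs, function(s) as.integer(s[[2L]]), 1L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  cue <- unlist(lapply(segs, function(s) rep_len(s[[3L]], s[[2L]])), use.names = FALSE)
  list(
    epochs = data.frame(label = labels, start = starts, end = ends,
                        stringsAsFactors = FALSE),
    cue_angle = cue,
    n_frames = sum(lens)
  )
}

# Ground-truth internal-drift profile: OU walk during darkness, exponential
# relaxation toward the cue-implied offset while a cue is displayed, zero at
# baseline. "Cue-implied" offset of epoch Ck is the cue displacement from
# its baseline position.
simulate_true_offset <- function(config, protocol) {
  n <- protocol$n_frames
  fr <- config$frame_rate
  dt <- 1 / fr
  set.seed(substream_seed(config$seed, "offset"))
  off <- numeric(n)
  rho <- exp(-dt / config$drift_tau)
  sd_innov <- config$drift_sd * sqrt(1 - rho^2)
  reset_rho <- exp(-dt / config$reset_tau)
  cur <- 0
  for (i in seq_len(nrow(protocol$epochs))) {
    ep <- protocol$epochs[i, ]
    idx <- ep$start:ep$end
    if (startsWith(ep$label, "D")) {
      # darkness: OU drift mean-reverting toward the baseline offset (0),
      # i.e. controllable wander plus a weak baseline attraction
      cur <- wrap_angle(cur)
      innov <- stats::rnorm(length(idx), 0, sd_innov)
      for (j in seq_along(idx)) {
        cur <- rho * cur + innov[j]
        off[idx[j]] <- cur
      }
    } else if (ep$label == "baseline") {
      off[idx] <- 0
      cur <- 0
    } else {
      # cue displayed: relax toward cue displacement from baseline
      target <- if (ep$label == "rotation") {
        unwrap_angle(protocol$cue_angle[idx])
      } else {
        rep(unwrap_angle(protocol$cue_angle[idx])[1], length(idx))
      }
      curu <- cur
      for (j in seq_along(idx)) {
        tgt <- target[j]
        # relax on the unwrapped circle toward the nearest representation
        tgt <- curu + wrap_angle(tgt - curu)
        curu <- tgt + (curu - tgt) * reset_rho
        off[idx[j]] <- curu
      }
      cur <- off[idx[length(idx)]]
    }
  }
  wrap_angle(off)
}

# von Mises tuning value (peak-normalized) at angle theta for pfd, kappa
von_mises_bump <- function(theta_deg, pfd_deg, kappa) {
  exp(kappa * (cos((theta_deg - pfd_deg) * pi / 180) - 1))
}

#' Generate a synthetic population recording from a trajectory
#'
#' For HD neuron `i`, the expected activity at frame `t` is
#' `gain(t) * f_i(wrap(hd(t) + offset(t)))`, a von Mises bump `f_i` centred
#' on the neuron's preferred firing direction and evaluated at the internal
#' head direction. Non-HD neurons have a direction-independent mean.
#' Realized activity is drawn from a zero-inflated gamma with that mean:
#' an exact zero with probability `p_zero`, otherwise gamma with fixed
#' shape and scale chosen so the mixture mean matches.
#'
#' @param config a [synth_config()].
#' @param hd_series measured head direction per frame, degrees.
#' @param true_gain per-frame gain multiplier (>= 0); default all 1.
#' @param true_offset per-frame internal-minus-measured discrepancy
#'   (degrees); default all 0.
#' @param cue_angle optional cue channel (degrees / `CUE_OFF`).
#' @param epochs optional epoch table.
#' @return list with `recording` (a `population_recording`: `activity`
#'   neurons x frames, `measured_hd`, `cue_angle`, `epochs`, `frame_rate`)
#'   and `truth` (`true_pfd`, `true_is_hd`, `true_kappa`, `true_peak`,
#'   `baseline_rate`, `true_gain`, `true_offset`).
#' @export
generate_population <- function(config, hd_series, true_gain = NULL,
                                true_offset = NULL, cue_angle = NULL,
                                epochs = NULL) {
  stopifnot(inherits(config, "synth_config"))
  n_frames <- length(hd_series)
  if (is.null(true_gain)) true_gain <- rep(1, n_frames)
  if (is.null(true_offset)) true_offset <- rep(0, n_frames)
  if (length(true_gain) != n_frames || length(true_offset) != n_frames)
    stop("hd_series, true_gain and true_offset must have equal length")
  if (any(true_gain < 0)) stop("true_gain must be >= 0")

  n <- config$n_neurons
  set.seed(substream_seed(config$seed, "cells"))
  n_hd <- round(config$frac_hd * n)
  is_hd <- rep(FALSE, n)
  if (n_hd > 0) is_hd[seq_len(n_hd)] <- TRUE
  # PFDs tile the circle evenly with jitter
  pfd <- rep(NA_real_, n)
  if (n_hd > 0) {
    base <- seq(-180, 180, length.out = n_hd + 1L)[seq_len(n_hd)]
    pfd[is_hd] <- wrap_angle(base + stats::runif(n_hd, -180 / max(n_hd, 1), 180 / max(n_hd, 1)))
  }
  kappa <- stats::runif(n, config$kappa_range[1], config$kappa_range[2])
  peak <- stats::runif(n, config$peak_rate_range[1], config$peak_rate_range[2])
  # direction-independent mean of non-HD cells: a fraction of their "peak"
  flat_rate <- peak * 0.3

  internal <- wrap_angle(hd_series + true_offset)
  mu <- matrix(0, nrow = n, ncol = n_frames)
  for (i in seq_len(n)) {
    mu[i, ] <- if (is_hd[i]) {
      peak[i] * von_mises_bump(internal, pfd[i], kappa[i])
    } else {
      rep(flat_rate[i], n_frames)
    }
  }
  mu <- sweep(mu, 2L, true_gain, `*`)

  if (config$noise == "none") {
    activity <- mu
  } else {
    set.seed(substream_seed(config$seed, "emission"))
    p0 <- config$zig_params$p_zero
    shp <- config$zig_params$shape
    activity <- matrix(0, nrow = n, ncol = n_frames)
    if (p0 < 1) {
      nz <- matrix(stats::runif(n * n_frames) >= p0, nrow = n)
      scale_mat <- mu / ((1 - p0) * shp)
      draws <- stats::rgamma(sum(nz), shape = shp, scale = 1) * scale_mat[nz]
      activity[nz] <- draws
    }
  }

  rec <- population_recording(
    activity = activity, measured_hd = wrap_angle(hd_series),
    cue_angle = cue_angle, epochs = epochs, frame_rate = config$frame_rate
  )
  truth <- list(
    true_pfd = pfd, true_is_hd = is_hd, true_kappa = kappa,
    true_peak = peak, baseline_rate = ifelse(is_hd, peak, flat_rate),
    true_gain = true_gain, true_offset = true_offset
  )
  list(recording = rec, truth = truth)
}

#' Construct a population-recording object
#'
#' Container for one session: non-negative deconvolved activity
#' (neurons x frames), measured head direction, cue channel and epoch
#' schedule.
#'
#' @param activity neurons x frames matrix, non-negative.
#' @param measured_hd degrees per frame in `[-180, 180)`.
#' @param cue_angle degrees per frame or `CUE_OFF`; default all 0.
#' @param epochs data.frame (`label`, `start`, `end`) of disjoint epochs
#'   covering all frames; default one `baseline` epoch.
#' @param frame_rate Hz.
#' @return object of class `population_recording`.
#' @export
population_recording <- function(activity, measured_hd, cue_angle = NULL,
                                 epochs = NULL, frame_rate = 30) {
  activity <- as.matrix(activity)
  n_frames <- ncol(activity)
  if (length(measured_hd) != n_frames)
    stop("measured_hd length must equal ncol(activity)")
  if (any(activity < 0)) stop("activity must be non-negative")
  if (is.null(cue_angle)) cue_angle <- rep(0, n_frames)
  if (length(cue_angle) != n_frames)
    stop("cue_angle length must equal ncol(activity)")
  if (is.null(epochs))
    epochs <- data.frame(label = "baseline", start = 1L, end = n_frames,
                         stringsAsFactors = FALSE)
  idx <- unlist(mapply(seq, epochs$start, epochs$end, SIMPLIFY = FALSE))
  if (length(idx) != n_frames || anyDuplicated(idx) || !setequal(idx, seq_len(n_frames)))
    stop("epochs must be disjoint and cover all frames")
  structure(
    list(activity = activity, measured_hd = wrap_angle(measured_hd),
         cue_angle = cue_angle, epochs = epochs, frame_rate = frame_rate),
    class = "population_recording"
  )
}

#' @export
print.population_recording <- function(x, ...) {
  cat(sprintf(
    "<population_recording> %d neurons x %d frames @ %g Hz (%.1f min), epochs: %s\n",
    nrow(x$activity), ncol(x$activity), x$frame_rate,
    ncol(x$activity) / x$frame_rate / 60,
    paste(x$epochs$label, collapse = " ")
  ))
  invisible(x)
}

#' Simulate a complete synthetic session
#'
#' Convenience wrapper tying together [build_protocol()],
#' [simulate_trajectory()], the ground-truth gain/drift profiles and
#' [generate_population()]. Ground-truth internal drift is an
#' Ornstein-Uhlenbeck walk during darkness, zero at baseline and an
#' exponential relaxation toward the cue-implied offset during cue epochs.
#'
#' @param config a [synth_config()].
#' @return list with `recording` and `truth` as in [generate_population()].
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  proto <- build_protocol(config)
  hd <- simulate_trajectory(config, n_frames = proto$n_frames)
  gain <- config$gain_profile
  if (is.null(gain)) gain <- rep(1, proto$n_frames)
  if (length(gain) != proto$n_frames)
    stop("gain_profile length must equal the protocol frame count (",
         proto$n_frames, ")")
  off <- if (config$protocol == "baseline_only") rep(0, proto$n_frames)
         else simulate_true_offset(config, proto)
  generate_population(config, hd, true_gain = gain, true_offset = off,
                      cue_angle = proto$cue_angle, epochs = proto$epochs)
}

#' Frames belonging to an epoch label
#'
#' @param rec a `population_recording` (or anything with an `epochs` table).
#' @param label epoch label, e.g. `"baseline"`, `"D1"`, `"C2"`; may be a
#'   vector.
#' @return integer frame indices.
#' @export
epoch_frames <- function(rec, label) {
  ep <- rec$epochs[rec$epochs$label %in% label, , drop = FALSE]
  if (nrow(ep) == 0L) return(integer(0))
  unlist(mapply(seq, ep$start, ep$end, SIMPLIFY = FALSE), use.names = FALSE)
}

#' Three-frame smoothed firing activity
#'
#' The raw deconvolved traces smoothed with a centred 3-frame moving
#' average; the "firing activity" used by tuning curves, gain estimation
#' and the bump reconstruction.
#'
#' @param rec a `population_recording`.
#' @param width smoothing width in frames (default 3).
#' @return matrix of the same dimension as `rec$activity`.
#' @export
firing_activity <- function(rec, width = 3) {
  t(apply(rec$activity, 1L, moving_average, width = width))
}
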