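# Offset and drift analysis: the offset is the wrapped angular difference
# between measured and decoded head direction, Offset(t) =
# angdiff(theta_decoded, theta_measured); its time course defines drift,
# reset events (rotations of the internal representation toward a displaced
# cue) and darkness drift statistics.

#' Offset trace between measured and decoded head direction
#'
#' Both inputs are circularly smoothed with a 20-frame moving average
#' before the wrapped difference `measured - decoded` is taken. Worked
#' sign convention: `decoded = measured - 90` gives offset `+90`.
#' Optionally a 300-frame (~10 s) low-frequency version is added for
#' darkness drift analyses.
#'
#' @param measured_hd measured head direction, degrees.
#' @param decoded_hd decoded head direction, degrees (may contain `NA`).
#' @param frame_rate Hz (used by [drift_speed()] downstream).
#' @param smooth input smoothing width in frames (default 20).
#' @param lowfreq if `TRUE`, also compute `offset_lowfreq` with a 300-frame
#'   moving average.
#' @param lowfreq_width width of the low-frequency filter (default 300).
#' @return object of class `offset_trace`: `offset` (deg, wrapped),
#'   `offset_lowfreq` (or `NULL`), `drift_speed` (deg/s), `frame_rate`.
#' @export
compute_offset <- function(measured_hd, decoded_hd, frame_rate = 30,
                           smooth = 20, lowfreq = FALSE,
                           lowfreq_width = 300) {
  if (length(measured_hd) != length(decoded_hd))
    stop("measured and decoded series must have equal length")
  m <- circ_moving_average(measured_hd, smooth)
  d <- circ_moving_average(decoded_hd, smooth)
  offset <- ang_diff(d, m)
  lf <- if (lowfreq) circ_moving_average(offset, lowfreq_width) else NULL
  ds <- if (length(offset) >= 20) drift_speed(offset, frame_rate = frame_rate)
        else rep(NA_real_, length(offset))
  structure(
    list(offset = offset, offset_lowfreq = lf, drift_speed = ds,
         frame_rate = frame_rate, smooth = smooth),
    class = "offset_trace"
  )
}

#' Drift speed by sliding linear regression
#'
#' Unwraps the offset and fits a least-squares line over a sliding
#' 20-frame window; the slope at the window centre, converted to degrees
#' per second, is the drift speed. Implemented as a convolution with the
#' exact regression weights, so it matches `lm()` on every interior
#' window. Edges (half a window) are `NA`.
#'
#' @param offset wrapped offset series, degrees (an `offset_trace` is also
#'   accepted).
#' @param window regression window in frames (default 20).
#' @param frame_rate Hz.
#' @return deg/s series of the same length.
#' @export
drift_speed <- function(offset, window = 20, frame_rate = 30) {
  if (inherits(offset, "offset_trace")) offset <- offset$offset
  window <- as.integer(window)
  n <- length(offset)
  if (window > n) stop("regression window exceeds series length")
  if (window < 2L) stop("regression window must be >= 2 frames")
  x <- unwrap_angle(offset)
  k <- seq_len(window) - (window + 1) / 2      # centred sample offsets
  w <- k / sum(k^2)                            # slope = sum(w * x[window])
  slope <- as.numeric(stats::filter(x, rev(w), sides = 2L))
  # align even windows with the movmean convention (one extra sample back)
  if (window %% 2L == 0L) slope <- c(NA_real_, slope[-length(slope)])
  slope * frame_rate
}

#' Angular head velocity from a heading series
#'
#' Same sliding-regression estimator as [drift_speed()] applied to the
#' (circularly smoothed) measured head direction.
#'
#' @param hd_series headings in degrees.
#' @param frame_rate Hz.
#' @param window regression window in frames.
#' @param smooth pre-smoothing width in frames.
#' @return deg/s series.
#' @export
angular_velocity <- function(hd_series, frame_rate = 30, window = 20,
                             smooth = 20) {
  drift_speed(circ_moving_average(hd_series, smooth), window = window,
              frame_rate = frame_rate)
}

#' Extract reset events at cue onsets
#'
#' One event per cue-display epoch (labels starting with `"C"`):
#' pre-cue offset (circular mean over the 50 frames before onset),
#' stabilized offset (circular mean over the final `stabilize_s` seconds of
#' the cue epoch), reset range `|wrap(stabilized - pre_cue)|`, and the
#' onset-referenced offset trajectory over the first `traj_frames` frames
#' after onset. Events whose cue epoch is shorter than the stabilization
#' window or the trajectory window are flagged and excluded from
#' `trajectories`.
#'
#' @param offset an `offset_trace` (or plain wrapped offset vector).
#' @param epochs epoch table (`label`, `start`, `end`).
#' @param frame_rate Hz.
#' @param traj_frames trajectory window after onset (default 1450).
#' @param pre_frames pre-cue averaging window (default 50, ~1.67 s).
#' @param stabilize_s stabilization window at the epoch end, seconds
#'   (default 30).
#' @return object of class `reset_events`: `events` data.frame
#'   (`label`, `onset_frame`, `pre_cue_offset`, `stabilized_offset`,
#'   `reset_range`, `included`) and `trajectories` (matrix, one row per
#'   included event, onset-referenced degrees).
#' @export
extract_reset_events <- function(offset, epochs, frame_rate = 30,
                                 traj_frames = 1450, pre_frames = 50,
                                 stabilize_s = 30) {
  off <- if (inherits(offset, "offset_trace")) offset$offset else offset
  cue_ep <- epochs[startsWith(epochs$label, "C"), , drop = FALSE]
  if (nrow(cue_ep) == 0L)
    return(structure(list(events = data.frame(), trajectories = NULL),
                     class = "reset_events"))
  stab_frames <- round(stabilize_s * frame_rate)
  rows <- list()
  trajs <- list()
  for (i in seq_len(nrow(cue_ep))) {
    ep <- cue_ep[i, ]
    onset <- ep$start
    ep_len <- ep$end - ep$start + 1L
    pre_idx <- max(1L, onset - pre_frames):(onset - 1L)
    pre <- circ_mean(off[pre_idx], na.rm = TRUE)
    ok <- ep_len >= stab_frames && (onset + traj_frames - 1L) <= length(off)
    stab <- if (ep_len >= stab_frames) {
      circ_mean(off[(ep$end - stab_frames + 1L):ep$end], na.rm = TRUE)
    } else NA_real_
    rng <- if (is.na(stab)) NA_real_ else abs(ang_diff(pre, stab))
    rows[[i]] <- data.frame(
      label = ep$label, onset_frame = onset, pre_cue_offset = pre,
      stabilized_offset = stab, reset_range = rng, included = ok,
      stringsAsFactors = FALSE
    )
    if (ok) {
      seg <- unwrap_angle(off[onset:(onset + traj_frames - 1L)])
      trajs[[length(trajs) + 1L]] <- seg - seg[1L]
    }
  }
  ev <- do.call(rbind, rows)
  traj_mat <- if (length(trajs)) do.call(rbind, trajs) else NULL
  if (!is.null(traj_mat)) rownames(traj_mat) <- ev$label[ev$included]
  structure(list(events = ev, trajectories = traj_mat),
            class = "reset_events")
}

#' Select reset events within a range group
#'
#' E.g. the 90-degree-centred group uses `range = c(70, 110)`.
#'
#' @param events a `reset_events`.
#' @param range numeric length-2 inclusive interval for `reset_range`.
#' @return a filtered `reset_events`.
#' @export
filter_reset_range <- function(events, range = c(70, 110)) {
  keep <- !is.na(events$events$reset_range) &
    events$events$reset_range >= range[1] &
    events$events$reset_range <= range[2]
  tr_keep <- keep[events$events$included]
  structure(
    list(events = events$events[keep, , drop = FALSE],
         trajectories = events$trajectories[tr_keep, , drop = FALSE]),
    class = "reset_events"
  )
}

# Lloyd k-means with city-block (L1) distance: component-wise median
# centroid updates, many random restarts, best total point-to-centroid
# distance wins. Small and deterministic under a seed.
kmeans_l1 <- function(X, k, replicates = 50, max_iter = 100, seed = 1L) {
  n <- nrow(X)
  set.seed(seed)
  best <- NULL
  for (rep in seq_len(replicates)) {
    centres <- X[sample.int(n, k), , drop = FALSE]
    assign_prev <- rep(0L, n)
    for (it in seq_len(max_iter)) {
      D <- vapply(seq_len(k), function(j)
        rowSums(abs(sweep(X, 2L, centres[j, ]))), numeric(n))
      assign <- max.col(-D, ties.method = "first")
      if (identical(assign, assign_prev)) break
      assign_prev <- assign
      for (j in seq_len(k)) {
        members <- X[assign == j, , drop = FALSE]
        if (nrow(members) == 0L) {
          centres[j, ] <- X[sample.int(n, 1L), ]
        } else {
          centres[j, ] <- apply(members, 2L, stats::median)
        }
      }
    }
    cost <- sum(D[cbind(seq_len(n), assign)])
    if (is.null(best) || cost < best$cost) {
      best <- list(assign = assign, centres = centres, cost = cost)
    }
  }
  best
}

#' Classify resets as fast or slow
#'
#' k-means (k = 2) on the onset-referenced reset trajectories with the
#' city-block (L1) distance and 50 random restarts. The cluster whose mean
#' trajectory reaches half of the cue shift earlier is labelled `"fast"`
#' (raw k-means labels are arbitrary).
#'
#' @param events a `reset_events` with at least 2 included trajectories, or
#'   a plain trajectory matrix (events x frames).
#' @param k number of clusters (default 2).
#' @param replicates random restarts (default 50).
#' @param seed integer seed (fixed seed gives identical labels).
#' @param half_shift half of the nominal cue shift, degrees (default 45).
#' @return list: `labels` (factor `fast`/`slow` per trajectory), `cluster`
#'   (raw indices), `centres`, `time_to_half` (frames, per cluster),
#'   `cost`.
#' @export
classify_fast_slow <- function(events, k = 2, replicates = 50, seed = 1L,
                               half_shift = 45) {
  X <- if (inherits(events, "reset_events")) events$trajectories else events
  if (is.null(X) || nrow(X) < k)
    stop("need at least ", k, " reset trajectories to cluster")
  if (max(stats::dist(X)) == 0)
    stop("all trajectories identical: clustering is degenerate")
  km <- kmeans_l1(X, k, replicates = replicates, seed = seed)
  # time for each cluster's mean trajectory to cover half the shift
  tth <- vapply(seq_len(k), function(j) {
    mt <- colMeans(X[km$assign == j, , drop = FALSE])
    hit <- which(abs(mt) >= half_shift)
    if (length(hit)) hit[1L] else ncol(X) + 1L
  }, numeric(1))
  fast_cluster <- which.min(tth)
  labels <- factor(ifelse(km$assign == fast_cluster, "fast", "slow"),
                   levels = c("fast", "slow"))
  list(labels = labels, cluster = km$assign, centres = km$centres,
       time_to_half = tth, cost = km$cost)
}

#' Darkness drift dispersion statistics
#'
#' For each epoch trace, computes the circular standard deviation of the
#' offset change from the epoch start, as a function of time, plus a
#' rank-sum comparison of end-of-epoch dispersion samples between groups
#' (e.g. darkness vs baseline).
#'
#' @param traces named list of offset vectors (degrees), one per epoch;
#'   low-frequency smoothed traces are expected.
#' @param groups character vector assigning each trace to a group
#'   (e.g. `"baseline"` / `"darkness"`).
#' @param tail_frac final fraction of each epoch summarized as its
#'   dispersion sample (default 0.25).
#' @return list: `dispersion` (list of per-epoch |change| series, deg),
#'   `epoch_dispersion` (one circular-sd summary per epoch),
#'   `test` (`wilcox.test` result, or `NULL` with < 2 groups).
#' @export
darkness_drift_stats <- function(traces, groups = NULL, tail_frac = 0.25) {
  change <- lapply(traces, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(numeric(0))
    ang_diff(x[1L], x)
  })
  epoch_disp <- vapply(change, function(d) {
    if (length(d) < 4L) return(NA_real_)
    tail_idx <- seq(from = ceiling(length(d) * (1 - tail_frac)), to = length(d))
    circ_sd(d[tail_idx])
  }, numeric(1))
  test <- NULL
  if (!is.null(groups) && length(unique(groups)) == 2L) {
    g <- split(epoch_disp, groups)
    a <- exclude_outliers(g[[1L]]); b <- exclude_outliers(g[[2L]])
    if (length(a) >= 1 && length(b) >= 1)
      test <- stats::wilcox.test(a, b)
  }
  list(dispersion = change, epoch_dispersion = epoch_disp, test = test)
}

#' Reflect a clockwise session into a counter-clockwise one
#'
#' Negates all angular quantities (head direction, cue angle) so clockwise
#' cue manipulations can be pooled with counter-clockwise ones. Applying it
#' twice is the identity.
#'
#' @param x a `population_recording`, an `offset_trace`, or a plain
#'   numeric vector of angles / angular velocities.
#' @return reflected object of the same class.
#' @export
reflect_clockwise <- function(x) {
  if (inherits(x, "population_recording")) {
    x$measured_hd <- wrap_angle(-x$measured_hd)
    x$cue_angle <- ifelse(is.na(x$cue_angle), x$cue_angle,
                          wrap_angle(-x$cue_angle))
    return(x)
  }
  if (inherits(x, "offset_trace")) {
    x$offset <- wrap_angle(-x$offset)
    if (!is.null(x$offset_lowfreq)) x$offset_lowfreq <- wrap_angle(-x$offset_lowfreq)
    x$drift_speed <- -x$drift_speed
    return(x)
  }
  if (is.numeric(x)) return(-x)
  stop("cannot reflect object of class ", paste(class(x), collapse = "/"))
}

#' Inclusion filter for cue-rotation sessions
#'
#' A session enters the post-rotation drift analysis only if its offset at
#' the start of the second darkness epoch falls inside the speed-dependent
#' window: `[-180,-145] U [145,180]` degrees for fast (3.0 deg/s) rotation
#' and `[-125,-55]` degrees for slow (1.5 deg/s) rotation.
#'
#' @param initial_offsets offset (deg) at the start of the second darkness,
#'   one per session.
#' @param speed_class `"fast"` or `"slow"` (scalar or per-session vector).
#' @return logical inclusion vector.
#' @export
filter_rotation_sessions <- function(initial_offsets,
                                     speed_class = c("fast", "slow")) {
  if (length(speed_class) == 1L)
    speed_class <- rep(match.arg(speed_class), length(initial_offsets))
  stopifnot(length(speed_class) == length(initial_offsets))
  vapply(seq_along(initial_offsets), function(i) {
    x <- wrap_angle(initial_offsets[i])
    if (speed_class[i] == "fast") {
      (x >= 145 & x <= 180) || (x >= -180 & x <= -145)
    } else {
      x >= -125 & x <= -55
    }
  }, logical(1))
}

#' Export a reset-event table to CSV
#'
#' @param events a `reset_events` (optionally with a `labels` column from
#'   [classify_fast_slow()] supplied via `classes`).
#' @param path output CSV path.
#' @param classes optional fast/slow labels for the included events.
#' @export
export_resets <- function(events, path, classes = NULL) {
  ev <- events$events
  ev$speed_class <- NA_character_
  if (!is.null(classes)) ev$speed_class[ev$included] <- as.character(classes)
  data.table::fwrite(ev, path)
  invisible(path)
}
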