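# HD-cell identification: occupancy-normalized tuning curves, a Gaussian
# stimulus signal centred on each neuron's preferred firing direction (PFD),
# Pearson scores against it, and a shuffle-calibrated classification
# threshold.

#' Occupancy-normalized head-direction tuning curve
#'
#' Sums firing activity per 1-degree bin of measured head direction, divides
#' by the occupancy time per bin, linearly interpolates across unvisited
#' bins (wrap-aware) and circularly smooths with a 50-degree moving average.
#' The PFD is the bin centre of the smoothed-curve maximum (ties broken
#' toward the smallest bin index).
#'
#' @param rec a `population_recording`.
#' @param neuron neuron index (row of the activity matrix).
#' @param frames frames to use (default all).
#' @param smooth_deg smoothing window in degrees (default 50).
#' @param activity optional pre-computed firing-activity matrix (the
#'   3-frame-smoothed traces from [firing_activity()]); computed on the fly
#'   if missing.
#' @return object of class `tuning_curve`: `rates` (360 values, a.u. per
#'   second of occupancy), `pfd` (deg), `neuron_id`.
#' @export
compute_tuning_curve <- function(rec, neuron, frames = NULL, smooth_deg = 50,
                                 activity = NULL) {
  if (is.null(frames)) frames <- seq_len(ncol(rec$activity))
  if (length(frames) == 0L) stop("frames subset is empty")
  act <- if (is.null(activity)) {
    moving_average(rec$activity[neuron, ], 3L)
  } else {
    activity[neuron, ]
  }
  bins <- hd_bin_index(rec$measured_hd[frames])
  occ <- tabulate(bins, nbins = 360L) / rec$frame_rate
  if (all(occ == 0)) stop("all-zero occupancy: no visited head-direction bins")
  sums <- rep(0, 360)
  agg <- rowsum(act[frames], group = bins)
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  rates <- ifelse(occ > 0, sums / occ, NA_real_)
  rates <- circ_interp_gaps(rates)
  smoothed <- circ_smooth_curve(rates, smooth_deg)
  pfd <- curve_argmax(smoothed)
  structure(
    list(rates = smoothed, raw_rates = rates, pfd = pfd, neuron_id = neuron),
    class = "tuning_curve"
  )
}

#' Gaussian stimulus signal for a preferred direction
#'
#' `stim(t) = exp(-angdiff(pfd, hd(t))^2 / (2 sigma^2))`: the measured head
#' direction passed through a narrow Gaussian kernel centred on the PFD
#' (s.d. 17 degrees by default). Equals 1 exactly when the head points at
#' the PFD.
#'
#' @param hd_series measured head direction, degrees.
#' @param pfd preferred firing direction, degrees.
#' @param sigma kernel standard deviation, degrees (> 0).
#' @return series in `(0, 1]`.
#' @export
stimulus_signal <- function(hd_series, pfd, sigma = 17) {
  if (sigma <= 0) stop("sigma must be > 0")
  d <- ang_diff(pfd, hd_series)
  exp(-d^2 / (2 * sigma^2))
}

#' HD score: Pearson correlation of activity with the stimulus signal
#'
#' Correlates the neuron's firing activity (3-frame-smoothed, z-scored; the
#' normalization is cosmetic since Pearson r is affine-invariant) with the
#' Gaussian stimulus signal of its PFD.
#'
#' @param rec a `population_recording`.
#' @param neuron neuron index.
#' @param pfd preferred direction in degrees (from the tuning curve).
#' @param sigma stimulus kernel s.d., degrees.
#' @param frames frames to use (default all).
#' @param activity optional pre-computed firing-activity matrix.
#' @return Pearson r; defined as 0 for zero-variance activity.
#' @export
hd_score <- function(rec, neuron, pfd, sigma = 17, frames = NULL,
                     activity = NULL) {
  if (is.null(frames)) frames <- seq_len(ncol(rec$activity))
  act <- if (is.null(activity)) {
    moving_average(rec$activity[neuron, ], 3L)
  } else {
    activity[neuron, ]
  }
  act <- act[frames]
  stim <- stimulus_signal(rec$measured_hd[frames], pfd, sigma)
  if (stats::sd(act) == 0 || stats::sd(stim) == 0) return(0)
  stats::cor(act, stim)
}

# Arg-max bin centre of a circular curve. Boxcar smoothing can leave exact
# plateaus (e.g. a single-bin tuning peak), so ties are resolved at the
# circular centre of the maximal run (lower bin on even runs); a fully flat
# curve degenerates to the first bin.
curve_argmax <- function(curve, tol = 1e-12) {
  top <- which(curve >= max(curve) - tol)
  centres <- hd_bin_centres()
  if (length(top) == 1L) return(centres[top])
  if (length(top) == length(curve)) return(centres[1L])
  mid <- circ_mean(centres[top])
  centres[hd_bin_index(mid)]
}

# Pearson correlation of stim with every circular shift of act, via FFT
# cross-correlation: r(lag) for all lags in O(T log T).
all_shift_correlations <- function(act, stim) {
  T <- length(act)
  sa <- stats::sd(act) * sqrt((T - 1) / T)
  ss <- stats::sd(stim) * sqrt((T - 1) / T)
  if (sa == 0 || ss == 0) return(rep(0, T))
  # sum_t act[t + lag] * stim[t] for lag = 0..T-1 (circular)
  cc <- Re(stats::fft(stats::fft(act) * Conj(stats::fft(stim)), inverse = TRUE)) / T
  (cc / T - mean(act) * mean(stim)) / (sa * ss)
}

#' Shuffle-calibrated HD-classification threshold
#'
#' Iterative procedure: starting from a high threshold, select all neurons
#' whose HD score exceeds it; for each, correlate `n_shuffles` circularly
#' time-shifted copies of its firing activity (shifts drawn uniformly from
#' `[T/20, 19T/20]`, preserving the temporal autocorrelation and the
#' marginal distribution) with its stimulus signal; pool the null scores;
#' if the threshold still exceeds the null 95th percentile, lower it by
#' `step` and repeat. Converges to approximately the null 95th percentile.
#'
#' @param rec_list one `population_recording` or a list of them (pooled as
#'   one recording group, e.g. one animal).
#' @param scores optional list of per-recording score tables as returned by
#'   [score_neurons()]; computed if missing.
#' @param start_r initial threshold (default 0.9).
#' @param step decrement per iteration.
#' @param n_shuffles circular shifts per neuron (>= 1).
#' @param percentile null percentile defining convergence (default 95).
#' @param frames optional frame subset applied to every recording.
#' @param seed integer seed for the random shifts.
#' @return list: `r_thresh`, `null_quantile`, `n_iterations`,
#'   `null_scores` (pooled final null distribution).
#' @export
shuffle_threshold <- function(rec_list, scores = NULL, start_r = 0.9,
                              step = 0.01, n_shuffles = 1000,
                              percentile = 95, frames = NULL, seed = 1L) {
  if (inherits(rec_list, "population_recording")) rec_list <- list(rec_list)
  if (n_shuffles < 1) stop("invalid argument: n_shuffles must be >= 1")
  if (is.null(scores)) scores <- lapply(rec_list, score_neurons, frames = frames)

  # lazily computed per-neuron null scores, cached across iterations
  null_cache <- vector("list", length(rec_list))
  for (k in seq_along(rec_list)) {
    null_cache[[k]] <- vector("list", nrow(rec_list[[k]]$activity))
  }
  set.seed(seed)
  neuron_null <- function(k, i) {
    if (!is.null(null_cache[[k]][[i]])) return(null_cache[[k]][[i]])
    rec <- rec_list[[k]]
    fr <- if (is.null(frames)) seq_len(ncol(rec$activity)) else frames
    act <- moving_average(rec$activity[i, ], 3L)[fr]
    stim <- stimulus_signal(rec$measured_hd[fr], scores[[k]]$pfd[i])
    T <- length(act)
    rall <- all_shift_correlations(act, stim)
    lo <- max(1L, floor(T / 20)); hi <- min(T - 1L, ceiling(19 * T / 20))
    shifts <- sample(lo:hi, n_shuffles, replace = TRUE)
    vals <- rall[shifts + 1L]
    null_cache[[k]][[i]] <<- vals
    vals
  }

  r_thresh <- start_r
  max_iter <- ceiling(start_r / step) + 10L
  for (iter in seq_len(max_iter)) {
    pool <- numeric(0)
    any_sel <- FALSE
    for (k in seq_along(rec_list)) {
      sel <- which(scores[[k]]$r > r_thresh)
      if (length(sel)) {
        any_sel <- TRUE
        pool <- c(pool, unlist(lapply(sel, function(i) neuron_null(k, i))))
      }
    }
    if (!any_sel) {
      r_thresh <- r_thresh - step
      next
    }
    q <- stats::quantile(pool, percentile / 100, names = FALSE)
    if (r_thresh <= q + step / 2) {
      return(list(r_thresh = r_thresh, null_quantile = q,
                  n_iterations = iter, null_scores = pool))
    }
    r_thresh <- r_thresh - step
  }
  stop("shuffle_threshold did not converge after ", max_iter,
       " iterations (last threshold ", signif(r_thresh, 3), ")")
}

#' Tuning curves and HD scores for every neuron
#'
#' @param rec a `population_recording`.
#' @param frames frame subset (default all).
#' @param sigma stimulus kernel s.d., degrees.
#' @return data.frame (`neuron_id`, `pfd`, `r`) with the list of
#'   `tuning_curve` objects in attribute `"curves"`.
#' @export
score_neurons <- function(rec, frames = NULL, sigma = 17) {
  n <- nrow(rec$activity)
  act <- firing_activity(rec)
  curves <- vector("list", n)
  pfd <- numeric(n)
  r <- numeric(n)
  for (i in seq_len(n)) {
    curves[[i]] <- compute_tuning_curve(rec, i, frames, activity = act)
    pfd[i] <- curves[[i]]$pfd
    r[i] <- hd_score(rec, i, pfd[i], sigma = sigma, frames = frames,
                     activity = act)
  }
  out <- data.frame(neuron_id = seq_len(n), pfd = pfd, r = r)
  attr(out, "curves") <- curves
  out
}

#' Classify HD cells by a correlation threshold
#'
#' @param rec a `population_recording`.
#' @param r_thresh classification threshold (e.g. from
#'   [shuffle_threshold()]).
#' @param scores optional pre-computed [score_neurons()] table.
#' @param frames frame subset used for tuning and scores.
#' @return object of class `tuning_curve_set`: `curves`, `scores`
#'   (data.frame with `neuron_id`, `pfd`, `r`, `is_hd`), `r_thresh`,
#'   `n_hd`, `frac_hd`.
#' @export
classify_hd_cells <- function(rec, r_thresh, scores = NULL, frames = NULL) {
  if (is.null(scores)) scores <- score_neurons(rec, frames = frames)
  curves <- attr(scores, "curves")
  scores$is_hd <- scores$r > r_thresh
  structure(
    list(curves = curves, scores = scores, r_thresh = r_thresh,
         n_hd = sum(scores$is_hd), frac_hd = mean(scores$is_hd)),
    class = "tuning_curve_set"
  )
}

#' @export
print.tuning_curve_set <- function(x, ...) {
  cat(sprintf(
    "<tuning_curve_set> %d neurons, %d HD cells (%.1f%%), r_thresh = %.3f\n",
    nrow(x$scores), x$n_hd, 100 * x$frac_hd, x$r_thresh
  ))
  invisible(x)
}

# 360 x n matrix of tuning-curve values (columns = neurons), restricted to
# the given neuron ids.
tuning_matrix <- function(tuning_set, neurons = NULL) {
  if (is.null(neurons)) neurons <- seq_along(tuning_set$curves)
  vapply(tuning_set$curves[neurons], function(cv) cv$rates, numeric(360))
}

#' Export per-neuron classification tables to CSV
#'
#' Writes `neurons.csv` (`neuron_id`, `pfd`, `r`, `is_hd`), `group.csv`
#' (`r_thresh`, `n_hd`, `frac_hd`) and `curves.csv` (one row per neuron,
#' 360 columns).
#'
#' @param tuning_set a `tuning_curve_set`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_tuning <- function(tuning_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(tuning_set$scores, file.path(dir, "neurons.csv"))
  data.table::fwrite(
    data.frame(r_thresh = tuning_set$r_thresh, n_hd = tuning_set$n_hd,
               frac_hd = tuning_set$frac_hd),
    file.path(dir, "group.csv")
  )
  cm <- t(tuning_matrix(tuning_set))
  colnames(cm) <- paste0("deg_", hd_bin_centres())
  data.table::fwrite(as.data.frame(cm), file.path(dir, "curves.csv"))
  invisible(dir)
}
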