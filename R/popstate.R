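# Network gain and the activity bump in the internal reference frame.
#
# The population model: instantaneous firing activity r_{i,t} =
# alpha_t * f_i(theta_t) + Gaussian noise, with f_i the baseline tuning
# curve evaluated at the *decoded* head direction theta_t and alpha_t a
# global gain applied homogeneously to all neurons. The maximum-likelihood
# estimate of alpha_t has the closed form dot(r, f) / dot(f, f); the noise
# variance cancels and never needs estimating.

#' Closed-form maximum-likelihood network gain for one frame
#'
#' `alpha_hat = sum(r * f) / sum(f^2)`, the minimizer of
#' `sum((r - alpha f)^2)`.
#'
#' @param activity_t activity vector (one value per neuron).
#' @param tuning_at_theta tuning-curve values of the same neurons at the
#'   decoded head direction.
#' @return scalar gain estimate.
#' @export
estimate_gain <- function(activity_t, tuning_at_theta) {
  if (length(activity_t) != length(tuning_at_theta))
    stop("activity and tuning vectors must have equal length")
  denom <- sum(tuning_at_theta^2)
  if (denom == 0) stop("all-zero tuning vector: gain undefined")
  sum(activity_t * tuning_at_theta) / denom
}

#' Per-frame network-gain trace, baseline-normalized
#'
#' Evaluates every HD cell's baseline tuning curve at the decoded head
#' direction of each frame, applies the closed-form gain estimate, smooths
#' with a 20-frame moving average and normalizes so the mean over the
#' baseline frames is exactly 1.
#'
#' @param rec a `population_recording`.
#' @param tuning_set a `tuning_curve_set` fitted on baseline data.
#' @param decoded a `decoded_trajectory` covering all frames of `rec` (or a
#'   plain numeric vector of decoded angles).
#' @param baseline_frames frames defining the normalization epoch (default:
#'   the epoch labelled `"baseline"`).
#' @param smooth moving-average width in frames (default 20).
#' @param neurons `"hd"` (default) to use classified HD cells, `"all"` for
#'   every recorded cell.
#' @param activity optional pre-computed firing-activity matrix.
#' @return object of class `gain_trace`: `alpha_raw`, `alpha_smooth`,
#'   `alpha_norm`, `baseline_mean`, `smoothing_window`.
#' @export
gain_trace <- function(rec, tuning_set, decoded, baseline_frames = NULL,
                       smooth = 20, neurons = c("hd", "all"),
                       activity = NULL) {
  neurons <- match.arg(neurons)
  dec_hd <- if (inherits(decoded, "decoded_trajectory")) decoded$map_hd else decoded
  T <- ncol(rec$activity)
  if (length(dec_hd) != T)
    stop("decoded head direction must cover every frame of the recording")
  if (is.null(baseline_frames)) baseline_frames <- epoch_frames(rec, "baseline")
  if (length(baseline_frames) == 0L) stop("empty baseline epoch")
  ids <- if (neurons == "hd") {
    which(tuning_set$scores$is_hd)
  } else {
    seq_len(nrow(tuning_set$scores))
  }
  if (length(ids) == 0L) stop("no neurons selected for gain estimation")
  Fmat <- tuning_matrix(tuning_set, ids)     # 360 x n
  act <- if (is.null(activity)) firing_activity(rec)[ids, , drop = FALSE]
         else activity[ids, , drop = FALSE]
  bin <- hd_bin_index(dec_hd)
  Ftheta <- t(Fmat[bin, , drop = FALSE])     # n x T tuning at decoded hd
  ok <- !is.na(dec_hd)
  denom <- colSums(Ftheta^2)
  alpha_raw <- rep(NA_real_, T)
  alpha_raw[ok & denom > 0] <-
    (colSums(act * Ftheta) / denom)[ok & denom > 0]
  alpha_smooth <- moving_average(alpha_raw, smooth)
  bl <- mean(alpha_smooth[baseline_frames], na.rm = TRUE)
  if (!is.finite(bl) || bl == 0) stop("baseline gain mean is degenerate")
  structure(
    list(alpha_raw = alpha_raw, alpha_smooth = alpha_smooth,
         alpha_norm = alpha_smooth / bl, baseline_mean = bl,
         smoothing_window = smooth),
    class = "gain_trace"
  )
}

#' Reconstruct the population activity bump
#'
#' Normalized weighted sum of tuning curves:
#' `A(theta) = sum_i f_i(theta) r_i / sum_i f_i(theta)`, evaluated on the
#' 360 standard bins. With activity supplied for several frames the result
#' is the 360 x T bump matrix.
#'
#' @param activity activity vector (one value per neuron) or neurons x T
#'   matrix.
#' @param tuning_set a `tuning_curve_set`; only its HD cells are used
#'   unless `neurons` selects otherwise.
#' @param neurons `"hd"` or `"all"`.
#' @return 360-vector (single frame) or 360 x T matrix.
#' @export
reconstruct_bump <- function(activity, tuning_set, neurons = c("hd", "all")) {
  neurons <- match.arg(neurons)
  ids <- if (neurons == "hd") which(tuning_set$scores$is_hd)
         else seq_len(nrow(tuning_set$scores))
  Fmat <- tuning_matrix(tuning_set, ids)   # 360 x n
  wsum <- rowSums(Fmat)
  if (any(wsum <= 0))
    stop("population does not cover the circle: sum of tuning curves is 0 at ",
         sum(wsum <= 0), " bins")
  if (is.matrix(activity)) {
    (Fmat %*% activity[ids, , drop = FALSE]) / wsum
  } else {
    as.numeric(Fmat %*% activity[ids]) / wsum
  }
}

#' Circular centre of mass of a bump column
#'
#' @param bump 360 non-negative values on the standard bins.
#' @return angle in degrees.
#' @export
bump_centre <- function(bump) {
  th <- hd_bin_centres() * pi / 180
  wrap_angle(atan2(sum(bump * sin(th)), sum(bump * cos(th))) * 180 / pi)
}

#' Correlation between network gain and embedding radius
#'
#' Pearson correlation and the R-squared of a least-squares linear fit of
#' radius against gain.
#'
#' @param gain numeric gain series (or a `gain_trace`, using `alpha_norm`).
#' @param radius embedding radius series of equal length.
#' @return list: `correlation`, `r_squared`, `slope`, `intercept`, `n`.
#' @export
gain_radius_correlation <- function(gain, radius) {
  if (inherits(gain, "gain_trace")) gain <- gain$alpha_norm
  if (length(gain) != length(radius)) stop("series lengths differ")
  ok <- is.finite(gain) & is.finite(radius)
  g <- gain[ok]; r <- radius[ok]
  if (length(g) < 3L) stop("too few finite paired observations")
  if (stats::sd(g) == 0 || stats::sd(r) == 0)
    stop("constant series: correlation undefined")
  rho <- stats::cor(g, r)
  slope <- rho * stats::sd(r) / stats::sd(g)
  list(
    correlation = rho,
    r_squared = rho^2, # simple regression: R^2 = squared Pearson r
    slope = slope,
    intercept = mean(r) - slope * mean(g),
    n = length(g)
  )
}

#' Export a gain trace to CSV
#'
#' @param gain a `gain_trace`.
#' @param path output CSV path (`frame`, `alpha_raw`, `alpha_norm`).
#' @export
export_gain <- function(gain, path) {
  data.table::fwrite(
    data.frame(frame = seq_along(gain$alpha_raw),
               alpha_raw = gain$alpha_raw, alpha_norm = gain$alpha_norm),
    path
  )
  invisible(path)
}
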