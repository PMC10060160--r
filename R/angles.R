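# Circular helpers. Convention used throughout the package: angles in
# degrees, wrapped to the half-open interval [-180, 180), counter-clockwise
# positive.

#' Wrap angles to [-180, 180) degrees
#'
#' @param x numeric vector of angles in degrees.
#' @return vector of the same length, wrapped to `[-180, 180)`.
#' @export
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Wrapped angular difference `b - a`
#'
#' Signed difference from `a` to `b`, wrapped to `[-180, 180)`. With
#' `a = decoded` and `b = measured` this is the offset convention used by
#' [compute_offset()]: `decoded = measured - 90` gives `+90`.
#'
#' @param a,b angles in degrees (vectors recycle).
#' @return wrapped difference in degrees.
#' @export
ang_diff <- function(a, b) {
  wrap_angle(b - a)
}

#' Circular mean of angles in degrees
#'
#' @param x angles in degrees.
#' @param na.rm drop missing values first.
#' @return circular mean in `[-180, 180)`; `NA` if no data.
#' @export
circ_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  rad <- x * pi / 180
  wrap_angle(atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi)
}

#' Circular standard deviation (degrees)
#'
#' Standard formula `sqrt(-2 log R)` on the mean resultant length `R`,
#' converted back to degrees.
#'
#' @inheritParams circ_mean
#' @export
circ_sd <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  rad <- x * pi / 180
  R <- sqrt(mean(sin(rad))^2 + mean(cos(rad))^2)
  R <- min(max(R, .Machine$double.eps), 1)
  sqrt(-2 * log(R)) * 180 / pi
}

#' Mean resultant length of angles in degrees
#'
#' @inheritParams circ_mean
#' @return scalar in `[0, 1]`.
#' @export
resultant_length <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  rad <- x * pi / 180
  sqrt(mean(sin(rad))^2 + mean(cos(rad))^2)
}

#' Unwrap a wrapped angular series
#'
#' Removes the +-360 discontinuities introduced by wrapping so that slopes
#' (drift speeds) can be estimated by ordinary regression.
#'
#' @param x angles in degrees, possibly wrapped.
#' @return continuous series with `x[1]` unchanged. `NA`s are carried
#'   through: the unwrapping resumes from the last finite value.
#' @export
unwrap_angle <- function(x) {
  n <- length(x)
  if (n <= 1L) return(x)
  ok <- which(!is.na(x))
  if (length(ok) <= 1L) return(x)
  out <- x
  xo <- x[ok]
  steps <- wrap_angle(diff(xo))
  out[ok] <- xo[1] + c(0, cumsum(steps))
  out
}

#' Centred moving average with truncated edges
#'
#' Plain (linear) moving average. For even widths the window extends one
#' sample further back than forward, matching the usual movmean convention.
#' Windows are truncated (renormalized) at the series edges, so constants are
#' preserved exactly everywhere.
#'
#' @param x numeric vector (may contain `NA`, which are excluded from the
#'   local average).
#' @param width window width in samples; `width <= 1` returns `x` unchanged.
#' @export
moving_average <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1L) return(x)
  n <- length(x)
  before <- width %/% 2L
  after <- width - before - 1L
  vals <- ifelse(is.na(x), 0, x)
  cnt <- as.numeric(!is.na(x))
  # padded cumulative sums give O(n) truncated-window means
  cs <- c(0, cumsum(vals))
  cc <- c(0, cumsum(cnt))
  lo <- pmax(seq_len(n) - before, 1L)
  hi <- pmin(seq_len(n) + after, n)
  s <- cs[hi + 1L] - cs[lo]
  k <- cc[hi + 1L] - cc[lo]
  out <- s / k
  out[k == 0] <- NA_real_
  out
}

#' Centred circular moving average of an angular time series
#'
#' Averages the sine and cosine components with [moving_average()] and
#' recombines, so wrap discontinuities do not corrupt the smoothing.
#'
#' @param x angles in degrees.
#' @param width window width in samples.
#' @return smoothed angles in `[-180, 180)`.
#' @export
circ_moving_average <- function(x, width) {
  if (as.integer(width) <= 1L) return(wrap_angle(x))
  rad <- x * pi / 180
  s <- moving_average(sin(rad), width)
  c_ <- moving_average(cos(rad), width)
  wrap_angle(atan2(s, c_) * 180 / pi)
}

#' Circular (wrap-around) moving average of a 360-bin curve
#'
#' Smooths a curve defined on the circle (one value per 1-degree bin) with a
#' boxcar that wraps around the ends. Because every window has full weight,
#' the curve mean is conserved exactly.
#'
#' @param x numeric vector treated as periodic (typically length 360).
#' @param width window width in bins; even widths take one extra bin on the
#'   left, as in [moving_average()].
#' @export
circ_smooth_curve <- function(x, width) {
  width <- as.integer(width)
  n <- length(x)
  if (width <= 1L || n <= 1L) return(x)
  before <- width %/% 2L
  after <- width - before - 1L
  idx <- c((n - before + 1L):n, 1L:n, 1L:after)
  if (before == 0L) idx <- c(1L:n, 1L:after)
  xp <- x[idx]
  cs <- c(0, cumsum(xp))
  pos <- seq_len(n) + before
  (cs[pos + after + 1L] - cs[pos - before]) / width
}

#' Interpolate missing bins of a circular curve
#'
#' Linear interpolation across gaps, wrap-aware. Used for unvisited
#' head-direction bins before smoothing a tuning curve.
#'
#' @param x numeric vector on the circle with `NA` gaps.
#' @return gap-filled vector; error if all values are missing.
#' @export
circ_interp_gaps <- function(x) {
  n <- length(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0L) stop("cannot interpolate: all bins are missing")
  if (length(ok) == n) return(x)
  if (length(ok) == 1L) {
    x[] <- x[ok]
    return(x)
  }
  # triple the circle, interpolate linearly, keep the middle copy
  xi <- stats::approx(
    x = c(ok - n, ok, ok + n), y = rep(x[ok], 3L),
    xout = seq_len(n)
  )$y
  xi
}

#' Remove outliers by the 3-standard-deviation rule
#'
#' Keeps data points inside `mean(x) +- 3 sd(x)`; the exclusion rule applied
#' uniformly across group comparisons in this package.
#'
#' @param x numeric vector.
#' @param n_sd number of standard deviations (default 3).
#' @return `x` with outliers removed (`NA`s dropped too).
#' @export
exclude_outliers <- function(x, n_sd = 3) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(x)
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x)
  x[x >= m - n_sd * s & x <= m + n_sd * s]
}

# Map angles (degrees) to 1-based indices of 360 integer-centred bins.
# Bin j covers [j - 0.5, j + 0.5) degrees for centres -180 .. 179.
hd_bin_index <- function(x) {
  centre <- wrap_angle(round(wrap_angle(x)))
  as.integer(centre) + 181L
}

# Bin centres in degrees for the 360 standard bins (index 1 -> -180).
hd_bin_centres <- function() {
  seq(-180, 179, by = 1)
}
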