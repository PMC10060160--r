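# Drift vector field in (drift-angle x drift-speed) state space, central
# symmetrization around the baseline point (0, 0), and forward-Euler
# streamline simulation demonstrating attraction to the baseline state.
#
# Grid conventions: x axis = drift angle, 18 bins of 20 degrees over
# [-180, 180]; y axis = drift speed over [-3, 3] deg/s in 20 bins. (A
# nominal per-bin width of 0.03 deg/s is inconsistent with that range and
# count; range and bin count are taken as authoritative, giving width
# 0.3 deg/s.)

#' Build a drift vector field
#'
#' Bins the aligned (drift angle, drift speed) samples on the standard
#' grid and stores the mean drift speed (`u`, the x-velocity: the rate of
#' change of drift angle) and mean drift acceleration (`v`, the
#' y-velocity) per bin. Empty bins are `NA`.
#'
#' @param drift_angle offset/drift angle samples, degrees in `[-180, 180)`.
#' @param drift_speed drift speed samples, deg/s.
#' @param drift_accel drift acceleration samples, deg/s^2; by default the
#'   [drift_acceleration()] of `drift_speed` is NOT computed here - pass
#'   aligned series.
#' @param x_bins,x_range angle binning (default 18 bins over
#'   `c(-180, 180)`).
#' @param y_bins,y_range speed binning (default 20 bins over `c(-3, 3)`).
#' @return object of class `vector_field`: matrices `u`, `v`, `counts`
#'   (y rows x x columns), bin centres, ranges.
#' @export
build_vector_field <- function(drift_angle, drift_speed, drift_accel,
                               x_bins = 18, x_range = c(-180, 180),
                               y_bins = 20, y_range = c(-3, 3)) {
  stopifnot(length(drift_angle) == length(drift_speed),
            length(drift_angle) == length(drift_accel))
  xw <- diff(x_range) / x_bins
  yw <- diff(y_range) / y_bins
  ok <- is.finite(drift_angle) & is.finite(drift_speed) & is.finite(drift_accel) &
    drift_speed >= y_range[1] & drift_speed < y_range[2]
  xi <- pmin(pmax(floor((wrap_angle(drift_angle[ok]) - x_range[1]) / xw) + 1L, 1L), x_bins)
  yi <- floor((drift_speed[ok] - y_range[1]) / yw) + 1L
  u <- v <- matrix(NA_real_, nrow = y_bins, ncol = x_bins)
  cnt <- matrix(0L, nrow = y_bins, ncol = x_bins)
  if (any(ok)) {
    flat <- (xi - 1L) * y_bins + yi
    agg <- rowsum(cbind(drift_speed[ok], drift_accel[ok], 1), group = flat)
    idx <- as.integer(rownames(agg))
    cnt[idx] <- as.integer(agg[, 3L])
    u[idx] <- agg[, 1L] / agg[, 3L]
    v[idx] <- agg[, 2L] / agg[, 3L]
  }
  structure(
    list(u = u, v = v, counts = cnt,
         x_centres = x_range[1] + (seq_len(x_bins) - 0.5) * xw,
         y_centres = y_range[1] + (seq_len(y_bins) - 0.5) * yw,
         x_range = x_range, y_range = y_range),
    class = "vector_field"
  )
}

#' Drift acceleration estimator
#'
#' Slope of the drift-speed series over the same sliding regression window
#' used for the speed itself, giving deg/s^2.
#'
#' @param drift_speed deg/s series.
#' @param window regression window in frames (default 20).
#' @param frame_rate Hz.
#' @export
drift_acceleration <- function(drift_speed, window = 20, frame_rate = 30) {
  n <- length(drift_speed)
  window <- as.integer(window)
  if (window > n) stop("regression window exceeds series length")
  k <- seq_len(window) - (window + 1) / 2
  w <- k / sum(k^2)
  x <- drift_speed
  x[is.na(x)] <- 0
  nav <- is.na(drift_speed)
  slope <- as.numeric(stats::filter(x, rev(w), sides = 2L))
  if (window %% 2L == 0L) slope <- c(NA_real_, slope[-length(slope)])
  slope <- slope * frame_rate
  # invalidate windows touching NA speed values
  bad <- as.numeric(stats::filter(as.numeric(nav), rep(1, window), sides = 2L)) > 0
  bad[is.na(bad)] <- TRUE
  if (window %% 2L == 0L) bad <- c(TRUE, bad[-length(bad)])
  slope[bad] <- NA_real_
  slope
}

#' Symmetrize a vector field around the origin
#'
#' Averages the field with its reflection across (0, 0) (positions and
#' vectors negated), exploiting the central symmetry of the cue-shift
#' design. The output satisfies `field(-x, -y) = -field(x, y)` exactly;
#' bins where only one of the pair is populated take the (negated)
#' populated value.
#'
#' @param field a `vector_field`.
#' @return symmetrized `vector_field` (idempotent).
#' @export
symmetrize <- function(field) {
  refl <- function(M) -M[rev(seq_len(nrow(M))), rev(seq_len(ncol(M))), drop = FALSE]
  avg <- function(A, B) {
    out <- (A + B) / 2
    only_a <- is.na(B) & !is.na(A)
    only_b <- is.na(A) & !is.na(B)
    out[only_a] <- A[only_a]
    out[only_b] <- B[only_b]
    out
  }
  field$u <- avg(field$u, refl(field$u))
  field$v <- avg(field$v, refl(field$v))
  field$counts <- field$counts + field$counts[rev(seq_len(nrow(field$counts))),
                                              rev(seq_len(ncol(field$counts)))]
  field
}

# fill NA bins with the nearest populated bin (x treated circularly)
fill_field <- function(M, x_centres, y_centres, circular_x = TRUE) {
  na_idx <- which(is.na(M), arr.ind = TRUE)
  if (nrow(na_idx) == 0L) return(M)
  ok_idx <- which(!is.na(M), arr.ind = TRUE)
  if (nrow(ok_idx) == 0L) return(M)
  out <- M
  nx <- ncol(M)
  for (r in seq_len(nrow(na_idx))) {
    dy <- ok_idx[, 1L] - na_idx[r, 1L]
    dx <- abs(ok_idx[, 2L] - na_idx[r, 2L])
    if (circular_x) dx <- pmin(dx, nx - dx)
    d <- dx^2 + dy^2
    out[na_idx[r, 1L], na_idx[r, 2L]] <- M[ok_idx[which.min(d), , drop = FALSE]]
  }
  out
}

# bilinear interpolation of a field matrix at (x, y); x circular
interp_field <- function(M, x_centres, y_centres, x, y) {
  nx <- length(x_centres); ny <- length(y_centres)
  xw <- x_centres[2L] - x_centres[1L]
  yw <- y_centres[2L] - y_centres[1L]
  # fractional index (circular in x)
  fx <- (wrap_angle(x) - x_centres[1L]) / xw
  fy <- (min(max(y, y_centres[1L]), y_centres[ny]) - y_centres[1L]) / yw
  i0 <- floor(fx); j0 <- floor(fy)
  tx <- fx - i0; ty <- fy - j0
  ix0 <- (as.integer(i0) %% nx) + 1L
  ix1 <- (as.integer(i0 + 1) %% nx) + 1L
  jy0 <- min(max(as.integer(j0) + 1L, 1L), ny)
  jy1 <- min(jy0 + 1L, ny)
  (1 - tx) * (1 - ty) * M[jy0, ix0] + tx * (1 - ty) * M[jy0, ix1] +
    (1 - tx) * ty * M[jy1, ix0] + tx * ty * M[jy1, ix1]
}

#' Simulate streamlines through a vector field
#'
#' Forward-Euler integration of `(x, y)` under bilinearly interpolated
#' `(u, v)` (missing bins filled from the nearest populated bin; the x
#' axis wraps). Starts outside the grid range are clipped and flagged.
#' The "stable regime" is the set of starts whose trajectory ends within
#' one bin of the origin.
#'
#' @param field a `vector_field` (typically symmetrized).
#' @param starts 2-column matrix of start points (x deg, y deg/s).
#' @param n_steps number of Euler steps (default 1000); 0 returns the
#'   starts.
#' @param dt step size in field time units (default 1).
#' @return list: `paths` (list of n_steps+1 x 2 matrices), `converged`
#'   (ends within one bin of the origin), `clipped`.
#' @export
streamlines <- function(field, starts, n_steps = 1000, dt = 1) {
  starts <- matrix(as.numeric(starts), ncol = 2L)
  U <- fill_field(field$u, field$x_centres, field$y_centres)
  V <- fill_field(field$v, field$x_centres, field$y_centres)
  yr <- field$y_range
  clipped <- starts[, 2L] < yr[1] | starts[, 2L] > yr[2]
  starts[, 2L] <- pmin(pmax(starts[, 2L], yr[1]), yr[2])
  xw <- field$x_centres[2L] - field$x_centres[1L]
  yw <- field$y_centres[2L] - field$y_centres[1L]
  paths <- vector("list", nrow(starts))
  converged <- logical(nrow(starts))
  for (s in seq_len(nrow(starts))) {
    p <- matrix(NA_real_, nrow = n_steps + 1L, ncol = 2L)
    p[1L, ] <- starts[s, ]
    xy <- starts[s, ]
    if (n_steps > 0) {
      for (st in seq_len(n_steps)) {
        du <- interp_field(U, field$x_centres, field$y_centres, xy[1L], xy[2L])
        dv <- interp_field(V, field$x_centres, field$y_centres, xy[1L], xy[2L])
        xy <- c(wrap_angle(xy[1L] + dt * du),
                min(max(xy[2L] + dt * dv, yr[1]), yr[2]))
        p[st + 1L, ] <- xy
      }
    }
    paths[[s]] <- p
    converged[s] <- abs(wrap_angle(xy[1L])) <= xw && abs(xy[2L]) <= yw
  }
  list(paths = paths, converged = converged, clipped = clipped)
}

#' Export a vector field to CSV
#'
#' @param field a `vector_field`.
#' @param path output CSV (`x_centre`, `y_centre`, `u`, `v`, `count`).
#' @export
export_vector_field <- function(field, path) {
  grid <- expand.grid(y = seq_along(field$y_centres),
                      x = seq_along(field$x_centres))
  data.table::fwrite(
    data.frame(
      x_centre = field$x_centres[grid$x], y_centre = field$y_centres[grid$y],
      u = field$u[cbind(grid$y, grid$x)], v = field$v[cbind(grid$y, grid$x)],
      count = field$counts[cbind(grid$y, grid$x)]
    ),
    path
  )
  invisible(path)
}
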