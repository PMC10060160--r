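# Bayesian decoding of the internal head direction from deconvolved
# calcium activity. Emission model: per neuron and per 1-degree bin a
# zero-inflated gamma (ZIG) - a point mass at zero plus a gamma-distributed
# positive part - which captures the stochasticity of deconvolved traces
# better than a Poisson count model. Neurons are assumed conditionally
# independent given the head direction, the prior over bins is uniform, and
# the log-likelihood matrix is smoothed over a centred 5-frame window.

ZIG_EPS_DEFAULT <- 1e-10

#' Fit per-bin zero-inflated-gamma emission models
#'
#' For every neuron and every 1-degree bin of measured head direction:
#' `p_zero` is the empirical fraction of activity values at (or numerically
#' below) zero; the gamma shape and scale come from method-of-moments on
#' the nonzero values. Binned moments (zero fraction, nonzero mean and
#' second moment) are circularly smoothed across neighbouring bins before
#' the parameters are derived, which regularizes sparsely occupied bins.
#' Degenerate bins are clamped: an all-zero bin gets `p_zero = 1` with
#' floor gamma parameters, a zero-variance bin gets the shape ceiling.
#'
#' @param rec a `population_recording` (training session).
#' @param frames training frames (default all); the measured head direction
#'   on these frames must cover the circle well.
#' @param smooth_deg width (degrees) of the circular moment smoothing.
#' @param eps activity at or below this value counts as zero.
#' @param shape_limits clamp interval for the gamma shape.
#' @param max_missing_frac error if more than this fraction of bins is
#'   unvisited.
#' @return object of class `emission_model`: 360 x n matrices `p_zero`,
#'   `shape`, `scale`, plus `eps` and `n_neurons`.
#' @export
fit_emission <- function(rec, frames = NULL, smooth_deg = 21,
                         eps = ZIG_EPS_DEFAULT,
                         shape_limits = c(0.05, 500),
                         max_missing_frac = 0.25) {
  if (is.null(frames)) frames <- seq_len(ncol(rec$activity))
  if (any(rec$activity < 0)) stop("activity must be non-negative")
  bins <- hd_bin_index(rec$measured_hd[frames])
  occ <- tabulate(bins, nbins = 360L)
  missing_bins <- which(occ == 0L)
  if (length(missing_bins) > max_missing_frac * 360) {
    stop("insufficient occupancy for emission fitting; unvisited bins: ",
         paste(hd_bin_centres()[missing_bins], collapse = ", "))
  }
  n <- nrow(rec$activity)
  p0 <- shp <- scl <- matrix(NA_real_, nrow = 360L, ncol = n)
  occ_s <- circ_smooth_curve(as.numeric(occ), smooth_deg)
  for (i in seq_len(n)) {
    a <- rec$activity[i, frames]
    nz <- a > eps
    # binned sufficient statistics
    zero_cnt <- tabulate(bins[!nz], nbins = 360L)
    s1 <- s2 <- rep(0, 360)
    if (any(nz)) {
      agg <- rowsum(cbind(a[nz], a[nz]^2), group = bins[nz])
      idx <- as.integer(rownames(agg))
      s1[idx] <- agg[, 1L]
      s2[idx] <- agg[, 2L]
    }
    # smooth the moments circularly (occupancy-weighted via smoothed sums)
    zc_s <- circ_smooth_curve(as.numeric(zero_cnt), smooth_deg)
    s1_s <- circ_smooth_curve(s1, smooth_deg)
    s2_s <- circ_smooth_curve(s2, smooth_deg)
    nz_s <- pmax(occ_s - zc_s, 0)
    p <- ifelse(occ_s > 0, zc_s / occ_s, NA_real_)
    m <- ifelse(nz_s > 0, s1_s / nz_s, NA_real_)
    v <- ifelse(nz_s > 0, pmax(s2_s / nz_s - m^2, 0), NA_real_)
    k <- ifelse(!is.na(v) & v > 0, m^2 / v, shape_limits[2])
    k <- pmin(pmax(k, shape_limits[1]), shape_limits[2])
    sc <- ifelse(!is.na(m) & m > 0, m / k, eps)
    # all-zero bins: point mass at zero with floor gamma part
    allz <- !is.na(p) & (nz_s == 0)
    k[allz] <- 1
    sc[allz] <- eps
    # unvisited bins: interpolate parameters around the circle
    unvis <- is.na(p)
    if (any(unvis)) {
      p <- circ_interp_gaps(p)
      k[unvis] <- NA_real_
      sc[unvis] <- NA_real_
      k <- circ_interp_gaps(k)
      sc <- circ_interp_gaps(sc)
    }
    # clamp p_zero away from 0/1 so log-likelihoods stay finite
    p0[, i] <- pmin(pmax(p, 1e-3), 1 - 1e-3)
    shp[, i] <- pmin(pmax(k, shape_limits[1]), shape_limits[2])
    scl[, i] <- pmax(sc, 1e-8)
  }
  structure(
    list(p_zero = p0, shape = shp, scale = scl, eps = eps, n_neurons = n),
    class = "emission_model"
  )
}

#' ZIG mixture mean per bin
#'
#' `(1 - p_zero) * shape * scale`, the model-implied expected activity.
#'
#' @param model an `emission_model`.
#' @return 360 x n matrix.
#' @export
emission_mean <- function(model) {
  (1 - model$p_zero) * model$shape * model$scale
}

#' Log-likelihood matrix over head-direction bins
#'
#' Column `t` holds, for each of the 360 bins, the summed log ZIG
#' likelihood of all neurons' activity at frame `t` (independence across
#' neurons), then a centred `smooth`-frame sum is applied per bin
#' (log-domain addition, i.e. a product of likelihoods across neighbouring
#' frames; windows are truncated at the edges). All recorded cells should
#' be included, not only classified HD cells, to avoid selection biases.
#'
#' @param rec a `population_recording`.
#' @param model an `emission_model` fitted on training data.
#' @param frames frames to decode (default all).
#' @param smooth temporal smoothing window in frames (default 5); 1 means
#'   no smoothing.
#' @param neurons neuron subset (default all in the model).
#' @return 360 x length(frames) matrix of (smoothed) log-likelihoods.
#' @export
loglik_matrix <- function(rec, model, frames = NULL, smooth = 5,
                          neurons = NULL) {
  if (is.null(frames)) frames <- seq_len(ncol(rec$activity))
  if (is.null(neurons)) neurons <- seq_len(model$n_neurons)
  if (any(rec$activity[neurons, frames] < 0))
    stop("activity must be non-negative")
  T <- length(frames)
  M <- matrix(0, nrow = 360L, ncol = T)
  lg <- lgamma(model$shape)
  for (i in neurons) {
    a <- rec$activity[i, frames]
    nz <- a > model$eps
    p <- model$p_zero[, i]; k <- model$shape[, i]; s <- model$scale[, i]
    if (any(!nz)) M[, !nz] <- M[, !nz] + log(p)
    if (any(nz)) {
      # log((1-p) * dgamma(a | k, s)) =
      #   log(1-p) - lgamma(k) - k log(s) + (k-1) log(a) - a/s
      const <- log(1 - p) - lg[, i] - k * log(s)
      coef <- cbind(const, k - 1, -1 / s)          # 360 x 3
      basis <- rbind(1, log(a[nz]), a[nz])         # 3 x Tnz
      M[, nz] <- M[, nz] + coef %*% basis
    }
  }
  if (smooth > 1) M <- smooth_loglik(M, smooth)
  M
}

# centred moving sum along columns, truncated at the edges
smooth_loglik <- function(M, window) {
  window <- as.integer(window)
  T <- ncol(M)
  before <- window %/% 2L
  after <- window - before - 1L
  cs <- cbind(0, t(apply(M, 1L, cumsum)))
  lo <- pmax(seq_len(T) - before, 1L)
  hi <- pmin(seq_len(T) + after, T)
  cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]
}

#' Maximum-likelihood decoded head direction
#'
#' Per-frame argmax of the log-likelihood matrix, reported as the bin
#' centre in degrees (ties broken toward the smallest bin).
#'
#' @param loglik 360 x T matrix (finite or `-Inf`).
#' @return object of class `decoded_trajectory`: `map_hd` (deg per frame),
#'   `loglik`, `smoothing_window` attribute if present.
#' @export
decode_map <- function(loglik) {
  if (any(apply(loglik, 2L, function(col) all(col == -Inf))))
    stop("column with all -Inf log-likelihood: nothing to decode")
  best <- max.col(t(loglik), ties.method = "first")
  structure(
    list(map_hd = hd_bin_centres()[best], loglik = loglik),
    class = "decoded_trajectory"
  )
}

#' Decode the internal head direction of a session
#'
#' Convenience wrapper: [loglik_matrix()] then [decode_map()].
#'
#' @inheritParams loglik_matrix
#' @return a `decoded_trajectory` (with `frames` recorded).
#' @export
decode_session <- function(rec, model, frames = NULL, smooth = 5,
                           neurons = NULL) {
  M <- loglik_matrix(rec, model, frames = frames, smooth = smooth,
                     neurons = neurons)
  out <- decode_map(M)
  out$frames <- if (is.null(frames)) seq_len(ncol(rec$activity)) else frames
  out$smoothing_window <- smooth
  out
}

#' Median absolute wrapped decoding error
#'
#' @param decoded_hd decoded head direction, degrees.
#' @param true_hd reference head direction, degrees.
#' @return median of `|angdiff|` in degrees.
#' @export
decode_mae <- function(decoded_hd, true_hd) {
  stats::median(abs(ang_diff(true_hd, decoded_hd)))
}
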