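# Gain tuning versus internal head direction and 2D heat maps over
# (angular head velocity x internal HD), with pixelwise rank-sum
# comparison between conditions.

#' Network-gain tuning curve over internal head direction
#'
#' Mean gain per 1-degree bin of internal head direction (expressed
#' relative to the baseline cue location), with empty bins interpolated
#' (wrap-aware, flagged) and the same 50-degree circular smoothing used
#' for firing tuning curves.
#'
#' @param gain gain series (or `gain_trace`; uses `alpha_norm`).
#' @param internal_hd internal head direction relative to the baseline cue
#'   location, degrees.
#' @param smooth_deg circular smoothing width (default 50).
#' @return list: `curve` (360 values), `raw` (pre-smoothing),
#'   `empty_bins` (bin centres that had no data), `counts`.
#' @export
gain_tuning_curve <- function(gain, internal_hd, smooth_deg = 50) {
  if (inherits(gain, "gain_trace")) gain <- gain$alpha_norm
  if (length(gain) != length(internal_hd)) stop("series lengths differ")
  ok <- is.finite(gain) & is.finite(internal_hd)
  bins <- hd_bin_index(internal_hd[ok])
  cnt <- tabulate(bins, nbins = 360L)
  sums <- rep(0, 360)
  agg <- rowsum(gain[ok], group = bins)
  sums[as.integer(rownames(agg))] <- agg[, 1L]
  raw <- ifelse(cnt > 0, sums / cnt, NA_real_)
  empty <- hd_bin_centres()[cnt == 0]
  raw_filled <- circ_interp_gaps(raw)
  list(curve = circ_smooth_curve(raw_filled, smooth_deg), raw = raw,
       empty_bins = empty, counts = cnt)
}

# bin edges/centres for the velocity axis
vel_axis <- function(v_range, v_bin) {
  edges <- seq(v_range[1], v_range[2], by = v_bin)
  list(edges = edges, centres = edges[-length(edges)] + v_bin / 2)
}

#' 2D heat map of a signal over (angular velocity x internal HD)
#'
#' Each pixel is a 2D bin of width `v_bin` deg/s (measured angular head
#' velocity, x) and height 1 degree (internal HD, y). A pixel's value is
#' the mean signal over all samples inside the overlapping averaging
#' window `[x - v_win, x + v_win]` x `[y - hd_win, y + hd_win]`; a 2D
#' Gaussian blur (s.d. `gauss_sd` pixels) is then applied, wrap-padded
#' along the HD axis and reflect-padded along the velocity axis, with
#' normalized convolution so unvisited pixels do not bleed. Callers should
#' pass signals pre-smoothed with a 20-frame moving average and velocity
#' from a 20-frame regression.
#'
#' @param signal signal series (gain, drift speed, ...).
#' @param velocity angular head velocity, deg/s.
#' @param internal_hd internal head direction (relative to baseline cue),
#'   degrees.
#' @param v_range velocity axis range, deg/s (default `c(-90, 90)`).
#' @param v_bin velocity pixel width (default 1.5 deg/s).
#' @param v_win velocity half-window of the averaging window (default 3).
#' @param hd_win HD half-window (default 15 degrees).
#' @param gauss_sd Gaussian blur s.d. in pixels (default 15); 0 disables.
#' @return object of class `heat_map`: `values` (velocity x HD matrix,
#'   blurred), `raw` (pre-blur window means), `counts` (samples per
#'   window), axes and binning metadata.
#' @export
build_heatmap <- function(signal, velocity, internal_hd,
                          v_range = c(-90, 90), v_bin = 1.5, v_win = 3,
                          hd_win = 15, gauss_sd = 15) {
  stopifnot(length(signal) == length(velocity),
            length(signal) == length(internal_hd))
  ok <- is.finite(signal) & is.finite(velocity) & is.finite(internal_hd) &
    velocity >= v_range[1] & velocity < v_range[2]
  ax <- vel_axis(v_range, v_bin)
  nv <- length(ax$centres)
  vi <- pmin(pmax(floor((velocity[ok] - v_range[1]) / v_bin) + 1L, 1L), nv)
  hi <- hd_bin_index(internal_hd[ok])
  # base-resolution sums/counts, then box-sum over the averaging window
  flat <- (hi - 1L) * nv + vi
  base_sum <- matrix(0, nrow = nv, ncol = 360L)
  base_cnt <- matrix(0, nrow = nv, ncol = 360L)
  agg <- rowsum(cbind(signal[ok], 1), group = flat)
  idx <- as.integer(rownames(agg))
  base_sum[idx] <- agg[, 1L]
  base_cnt[idx] <- agg[, 2L]
  rv <- round(v_win / v_bin)        # window half-width in velocity pixels
  rh <- round(hd_win)               # window half-height in HD pixels
  win_sum <- box_sum_2d(base_sum, rv, rh)
  win_cnt <- box_sum_2d(base_cnt, rv, rh)
  raw <- ifelse(win_cnt > 0, win_sum / win_cnt, NA_real_)
  values <- if (gauss_sd > 0) gauss_blur_2d(raw, gauss_sd) else raw
  structure(
    list(values = values, raw = raw, counts = win_cnt,
         v_centres = ax$centres, hd_centres = hd_bin_centres(),
         v_bin = v_bin, v_win = v_win, hd_win = hd_win,
         gauss_sd = gauss_sd, v_range = v_range),
    class = "heat_map"
  )
}

# 2D moving box sum with half-widths (rv rows, rh cols); rows (velocity)
# truncated at the borders, columns (HD) wrap around the circle.
box_sum_2d <- function(M, rv, rh) {
  nr <- nrow(M); nc <- ncol(M)
  # columns: circular -> pad with wrapped copies
  if (rh > 0) {
    Mp <- cbind(M[, (nc - rh + 1L):nc, drop = FALSE], M,
                M[, 1L:rh, drop = FALSE])
    cs <- t(apply(Mp, 1L, cumsum))
    cs <- cbind(0, cs)
    pos <- seq_len(nc) + rh
    M <- cs[, pos + rh + 1L, drop = FALSE] - cs[, pos - rh, drop = FALSE]
  }
  if (rv > 0) {
    cs <- apply(M, 2L, cumsum)
    cs <- rbind(0, cs)
    lo <- pmax(seq_len(nr) - rv, 1L)
    hi <- pmin(seq_len(nr) + rv, nr)
    M <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  }
  M
}

# separable Gaussian blur: rows (velocity) reflect-padded, columns (HD)
# wrap-padded; normalized convolution so NA pixels neither receive nor
# contribute weight.
gauss_blur_2d <- function(M, sd_px) {
  r <- max(1L, ceiling(3 * sd_px))
  kern <- stats::dnorm(seq(-r, r), sd = sd_px)
  kern <- kern / sum(kern)
  mask <- is.finite(M)
  V <- ifelse(mask, M, 0)
  W <- matrix(as.numeric(mask), nrow = nrow(M))
  blur_axis <- function(X, along_rows) {
    n <- if (along_rows) nrow(X) else ncol(X)
    # padded index vector: reflect for rows, wrap for columns
    if (along_rows) {
      pre <- pmin(pmax(r:1, 1L), n); post <- pmin(pmax(n:(n - r + 1L), 1L), n)
      idx <- c(pre, seq_len(n), post)
      Xp <- X[idx, , drop = FALSE]
      out <- matrix(0, nrow = n, ncol = ncol(X))
      for (j in seq_along(kern)) {
        out <- out + kern[j] * Xp[seq_len(n) + j - 1L, , drop = FALSE]
      }
    } else {
      idx <- c(((n - r + 1L):n), seq_len(n), 1L:r)
      if (r > n) { # tiny test maps: recycle the wrap
        idx <- ((seq(-r, n + r - 1L)) %% n) + 1L
      }
      Xp <- X[, idx, drop = FALSE]
      out <- matrix(0, nrow = nrow(X), ncol = n)
      for (j in seq_along(kern)) {
        out <- out + kern[j] * Xp[, seq_len(n) + j - 1L, drop = FALSE]
      }
    }
    out
  }
  Vb <- blur_axis(blur_axis(V, TRUE), FALSE)
  Wb <- blur_axis(blur_axis(W, TRUE), FALSE)
  out <- ifelse(Wb > 1e-12, Vb / Wb, NA_real_)
  out[!mask] <- NA_real_
  out
}

#' Pixelwise comparison of two heat maps
#'
#' Per pixel, a two-sided Wilcoxon rank-sum test between the raw samples
#' falling in that pixel's averaging window in map `a` versus map `b`
#' (the test uses the windowed samples, not blurred values). The
#' difference map is `a - b`; pixels with `p > alpha` are masked (`NaN`),
#' and with `positive_only = TRUE` negative differences are masked too
#' (the gain-map convention; drift-speed maps keep both signs).
#'
#' Both maps must carry their sample series: build them with
#' [heatmap_samples()] wrappers or pass `samples_a` / `samples_b`
#' explicitly as lists `(signal, velocity, internal_hd)`.
#'
#' @param map_a,map_b `heat_map` objects with identical binning.
#' @param samples_a,samples_b lists with elements `signal`, `velocity`,
#'   `internal_hd` holding the raw series each map was built from.
#' @param alpha significance level (default 0.001).
#' @param positive_only mask negative differences as well (default TRUE).
#' @return list: `difference` (masked `a - b`), `p_matrix`,
#'   `difference_raw` (unmasked).
#' @export
compare_heatmaps <- function(map_a, map_b, samples_a, samples_b,
                             alpha = 0.001, positive_only = TRUE) {
  if (!isTRUE(all.equal(map_a$v_centres, map_b$v_centres)) ||
      map_a$v_bin != map_b$v_bin || map_a$v_win != map_b$v_win ||
      map_a$hd_win != map_b$hd_win)
    stop("heat maps have mismatched binning")
  ga <- gather_window_samples(map_a, samples_a)
  gb <- gather_window_samples(map_b, samples_b)
  nv <- length(map_a$v_centres)
  pmat <- matrix(NA_real_, nrow = nv, ncol = 360L)
  for (p in seq_len(nv * 360L)) {
    xa <- ga[[p]]; xb <- gb[[p]]
    if (length(xa) >= 2L && length(xb) >= 2L) {
      pmat[p] <- suppressWarnings(
        stats::wilcox.test(xa, xb, exact = FALSE)$p.value
      )
    }
  }
  diff_raw <- map_a$values - map_b$values
  diff <- diff_raw
  diff[is.na(pmat) | pmat > alpha] <- NaN
  if (positive_only) diff[!is.na(diff_raw) & diff_raw < 0] <- NaN
  list(difference = diff, p_matrix = pmat, difference_raw = diff_raw)
}

# per-pixel lists of raw samples inside each averaging window
gather_window_samples <- function(map, samples) {
  v_range <- map$v_range; v_bin <- map$v_bin
  nv <- length(map$v_centres)
  ok <- is.finite(samples$signal) & is.finite(samples$velocity) &
    is.finite(samples$internal_hd) &
    samples$velocity >= v_range[1] & samples$velocity < v_range[2]
  vi <- pmin(pmax(floor((samples$velocity[ok] - v_range[1]) / v_bin) + 1L, 1L), nv)
  hi <- hd_bin_index(samples$internal_hd[ok])
  sig <- samples$signal[ok]
  rv <- round(map$v_win / v_bin)
  rh <- round(map$hd_win)
  # index samples by base pixel, then collect each pixel's window members
  by_base <- split(sig, factor((hi - 1L) * nv + vi,
                               levels = seq_len(nv * 360L)))
  out <- vector("list", nv * 360L)
  for (h in seq_len(360L)) {
    hcols <- ((h - 1L + seq(-rh, rh)) %% 360L) + 1L
    for (v in seq_len(nv)) {
      vrows <- seq(max(1L, v - rv), min(nv, v + rv))
      cells <- as.vector(outer(vrows, (hcols - 1L) * nv, `+`))
      out[[(h - 1L) * nv + v]] <- unlist(by_base[cells], use.names = FALSE)
    }
  }
  out
}

#' Export a heat map to CSV with a JSON binning sidecar
#'
#' @param map a `heat_map`.
#' @param path CSV path for the value matrix (velocity rows x HD columns);
#'   a `<path>.json` sidecar records the binning metadata.
#' @export
export_heatmap <- function(map, path) {
  vm <- as.data.frame(map$values)
  colnames(vm) <- paste0("deg_", map$hd_centres)
  data.table::fwrite(cbind(v_centre = map$v_centres, vm), path)
  meta <- map[c("v_bin", "v_win", "hd_win", "gauss_sd", "v_range")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
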