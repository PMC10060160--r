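# End-to-end orchestration: simulate (or load) a session, identify HD
# cells, decode, estimate gain, extract offset/reset statistics, and write
# every artifact to a session container with a JSON summary. All
# randomness flows from one master seed through named substreams.

#' Pipeline configuration
#'
#' @param synth a [synth_config()] describing the synthetic session, or
#'   `NULL` when `input` points at an existing container.
#' @param input optional path to a session container to analyse instead of
#'   simulating.
#' @param stages character vector of stages to run, in dependency order
#'   from `c("simulate", "identify", "decode", "gain", "resets")`;
#'   `"maps"`, `"field"` and `"embed"` are optional extras.
#' @param out output directory.
#' @param seed master seed.
#' @param r_thresh HD threshold; `NULL` runs [shuffle_threshold()] (with
#'   `n_shuffles` below).
#' @param n_shuffles shuffles for the threshold stage.
#' @param decode_smooth likelihood smoothing window, frames.
#' @return object of class `run_config`.
#' @export
run_config <- function(synth = synth_config(), input = NULL,
                       stages = c("simulate", "identify", "decode", "gain",
                                  "resets"),
                       out = tempfile("hdring_run_"), seed = 1L,
                       r_thresh = NULL, n_shuffles = 200,
                       decode_smooth = 5) {
  known <- c("simulate", "identify", "decode", "gain", "resets", "maps",
             "field", "embed")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  order <- match(stages, known)
  if (is.unsorted(order)) stop("stages must respect the dependency order")
  structure(
    list(synth = synth, input = input, stages = stages, out = out,
         seed = as.integer(seed), r_thresh = r_thresh,
         n_shuffles = n_shuffles, decode_smooth = decode_smooth),
    class = "run_config"
  )
}

#' Run the analysis pipeline
#'
#' Executes the configured stages and writes all artifacts under
#' `config$out`: the session container, per-neuron classification tables,
#' decoded trajectory, gain and offset traces, a reset-event table, and
#' `summary.json` (HD counts, decoder MAE against measured HD, gain
#' statistics) plus `run_log.txt` with stage timings. Re-running with the
#' same configuration and seed reproduces every output byte for byte.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the in-memory artifacts: `recording`,
#'   `truth`, `tuning`, `decoded`, `gain`, `offset`, `resets`, `summary`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out, "run_log.txt")
  cat("hdring pipeline\nstages:", paste(config$stages, collapse = ", "),
      "\nseed:", config$seed, "\n", file = log_path)
  tic <- function() proc.time()[["elapsed"]]
  log_stage <- function(name, t0) {
    cat(sprintf("%s: %.1f s\n", name, tic() - t0), file = log_path,
        append = TRUE)
  }
  res <- list()
  summary <- list(seed = config$seed)

  need <- function(artifact, stage) {
    if (is.null(res[[artifact]]))
      stop("stage '", stage, "' needs missing upstream artifact '",
           artifact, "'")
  }

  # --- simulate / load -----------------------------------------------------
  t0 <- tic()
  if ("simulate" %in% config$stages) {
    cfg <- config$synth
    cfg$seed <- substream_seed(config$seed, "synth")
    sess <- simulate_session(cfg)
    res$recording <- sess$recording
    res$truth <- sess$truth
    write_session(res$recording, file.path(out, "session"),
                  attrs = list(seed = config$seed, protocol = cfg$protocol))
    write_ground_truth(res$truth, file.path(out, "session"))
    summary$protocol <- cfg$protocol
  } else if (!is.null(config$input)) {
    res$recording <- read_session(config$input)
  }
  log_stage("simulate", t0)

  baseline <- epoch_frames(res$recording, "baseline")

  if ("identify" %in% config$stages) {
    t0 <- tic()
    need("recording", "identify")
    scores <- score_neurons(res$recording, frames = baseline)
    r_thresh <- config$r_thresh
    if (is.null(r_thresh)) {
      r_thresh <- shuffle_threshold(
        res$recording, scores = list(scores), frames = baseline,
        n_shuffles = config$n_shuffles,
        seed = substream_seed(config$seed, "shuffle")
      )$r_thresh
    }
    res$tuning <- classify_hd_cells(res$recording, r_thresh, scores = scores)
    export_tuning(res$tuning, file.path(out, "tuning"))
    summary$r_thresh <- r_thresh
    summary$n_hd <- res$tuning$n_hd
    summary$frac_hd <- res$tuning$frac_hd
    log_stage("identify", t0)
  }

  if ("decode" %in% config$stages) {
    t0 <- tic()
    need("recording", "decode")
    model <- fit_emission(res$recording, frames = baseline)
    res$decoded <- decode_session(res$recording, model,
                                  smooth = config$decode_smooth)
    data.table::fwrite(
      data.frame(frame = seq_along(res$decoded$map_hd),
                 decoded_hd = res$decoded$map_hd),
      file.path(out, "session", "decoded.csv")
    )
    summary$decoder_mae_baseline <- decode_mae(
      res$decoded$map_hd[baseline], res$recording$measured_hd[baseline]
    )
    log_stage("decode", t0)
  }

  if ("gain" %in% config$stages) {
    t0 <- tic()
    need("tuning", "gain"); need("decoded", "gain")
    res$gain <- gain_trace(res$recording, res$tuning, res$decoded,
                           baseline_frames = baseline)
    export_gain(res$gain, file.path(out, "session", "gain.csv"))
    g <- res$gain$alpha_norm
    summary$gain_mean <- mean(g, na.rm = TRUE)
    summary$gain_sd <- stats::sd(g, na.rm = TRUE)
    log_stage("gain", t0)
  }

  if ("resets" %in% config$stages) {
    t0 <- tic()
    need("decoded", "resets")
    res$offset <- compute_offset(res$recording$measured_hd,
                                 res$decoded$map_hd,
                                 frame_rate = res$recording$frame_rate,
                                 lowfreq = TRUE)
    data.table::fwrite(
      data.frame(frame = seq_along(res$offset$offset),
                 offset = res$offset$offset,
                 drift_speed = res$offset$drift_speed),
      file.path(out, "session", "offset.csv")
    )
    res$resets <- extract_reset_events(res$offset, res$recording$epochs,
                                       frame_rate = res$recording$frame_rate)
    export_resets(res$resets, file.path(out, "resets.csv"))
    summary$n_reset_events <- nrow(res$resets$events)
    summary$n_resets_included <- sum(res$resets$events$included)
    log_stage("resets", t0)
  }

  if ("embed" %in% config$stages) {
    t0 <- tic()
    need("recording", "embed")
    net <- build_network(nrow(res$recording$activity),
                         seed = substream_seed(config$seed, "polarnet"))
    net <- train_polarnet(net, res$recording$activity[, baseline],
                          res$recording$measured_hd[baseline],
                          seed = substream_seed(config$seed, "polarnet"))
    res$embedding <- polar_embed(net, res$recording$activity)
    data.table::fwrite(
      data.frame(frame = seq_along(res$embedding$theta_hat),
                 theta_hat = res$embedding$theta_hat,
                 radius_hat = res$embedding$radius_hat),
      file.path(out, "session", "embedding.csv")
    )
    log_stage("embed", t0)
  }

  summary_path <- file.path(out, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA)
  res$summary <- summary
  invisible(res)
}

#' Preset configuration for the cue-shift experiment
#'
#' A synthetic 2-min 90-degree cue-shift session analysed end to end
#' (identification, decoding, gain, resets).
#'
#' @param seed master seed.
#' @param out output directory.
#' @param n_neurons population size (scaled down by default for speed).
#' @export
preset_cue_shift <- function(seed = 1L, out = tempfile("hdring_fig2_"),
                             n_neurons = 80) {
  run_config(
    synth = synth_config(protocol = "two_min_shift", n_neurons = n_neurons,
                         seed = seed),
    stages = c("simulate", "identify", "decode", "gain", "resets"),
    out = out, seed = seed
  )
}
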