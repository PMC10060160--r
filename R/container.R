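# Hierarchical session container: one directory per session holding named
# datasets (CSV) plus an attributes.json. Dataset names mirror the
# conceptual layout /activity, /measured_hd, /cue_angle, /epochs, /decoded,
# /gain, /offset, /embedding; the plain-text representation keeps sessions
# portable across languages.

#' Write a session to a container directory
#'
#' @param rec a `population_recording`.
#' @param path container directory (created/overwritten).
#' @param attrs named list of extra attributes (seed, protocol, ...).
#' @return `path`, invisibly.
#' @export
write_session <- function(rec, path, attrs = list()) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(data.table::as.data.table(rec$activity),
                     file.path(path, "activity.csv"), col.names = FALSE)
  data.table::fwrite(data.frame(measured_hd = rec$measured_hd),
                     file.path(path, "measured_hd.csv"))
  data.table::fwrite(data.frame(cue_angle = rec$cue_angle),
                     file.path(path, "cue_angle.csv"))
  data.table::fwrite(rec$epochs, file.path(path, "epochs.csv"))
  jsonlite::write_json(
    c(list(frame_rate = rec$frame_rate,
           n_neurons = nrow(rec$activity),
           n_frames = ncol(rec$activity)), attrs),
    file.path(path, "attributes.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a session from a container directory
#'
#' @param path container directory written by [write_session()].
#' @return a `population_recording` with extra attributes in
#'   `attr(, "container_attrs")`.
#' @export
read_session <- function(path) {
  at <- jsonlite::read_json(file.path(path, "attributes.json"),
                            simplifyVector = TRUE)
  act <- as.matrix(data.table::fread(file.path(path, "activity.csv"),
                                     header = FALSE))
  dimnames(act) <- NULL
  rec <- population_recording(
    activity = act,
    measured_hd = data.table::fread(file.path(path, "measured_hd.csv"))$measured_hd,
    cue_angle = data.table::fread(file.path(path, "cue_angle.csv"))$cue_angle,
    epochs = as.data.frame(data.table::fread(file.path(path, "epochs.csv"))),
    frame_rate = at$frame_rate
  )
  attr(rec, "container_attrs") <- at
  rec
}

#' Write ground truth tables to CSV
#'
#' @param truth the `truth` element of [simulate_session()] output.
#' @param path container directory.
#' @export
write_ground_truth <- function(truth, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(
    data.frame(neuron_id = seq_along(truth$true_pfd),
               true_pfd = truth$true_pfd, true_is_hd = truth$true_is_hd,
               true_kappa = truth$true_kappa, true_peak = truth$true_peak),
    file.path(path, "ground_truth_cells.csv")
  )
  data.table::fwrite(
    data.frame(frame = seq_along(truth$true_gain),
               true_gain = truth$true_gain,
               true_offset = truth$true_offset),
    file.path(path, "ground_truth_frames.csv")
  )
  invisible(path)
}
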