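#' Construct a synchronized multimodal EEG-EMG recording
#'
#' The unit of raw data: a matrix of EEG channels and a matrix of surface EMG
#' channels sharing one clock and one sampling rate. Clinical spasm monitoring
#' uses a 25-channel scalp montage (extended 10-20) together with four EMG
#' electrodes over the deltoid and quadriceps muscles bilaterally, sampled at
#' 1024 Hz; any channel counts and any rate are accepted here.
#'
#' @param eeg numeric matrix, channels x samples (microvolt scale).
#' @param emg numeric matrix, channels x samples, same number of samples.
#' @param fs sampling rate in samples/second.
#' @param eeg_channels,emg_channels character vectors of channel labels whose
#'   lengths must match the row counts of `eeg` and `emg`.
#' @param subject_id,recording_id identifier strings.
#'
#' @return An object of class `multimodal_recording`.
#' @export
multimodal_recording <- function(eeg, emg, fs = 1024,
                                 eeg_channels = NULL, emg_channels = NULL,
                                 subject_id = "s1", recording_id = "r1") {
  eeg <- as.matrix(eeg)
  emg <- as.matrix(emg)
  if (is.null(eeg_channels)) eeg_channels <- paste0("EEG", seq_len(nrow(eeg)))
  if (is.null(emg_channels)) emg_channels <- paste0("EMG", seq_len(nrow(emg)))
  rec <- structure(
    list(
      eeg = eeg, emg = emg, fs = fs,
      eeg_channels = as.character(eeg_channels),
      emg_channels = as.character(emg_channels),
      subject_id = as.character(subject_id),
      recording_id = as.character(recording_id)
    ),
    class = "multimodal_recording"
  )
  validate_recording(rec)
  rec
}

#' Validate a multimodal recording
#'
#' Checks the structural invariants: equal sample counts across modalities,
#' positive sampling rate, label lists matching channel counts, and finite
#' signal values.
#'
#' @param rec a `multimodal_recording`.
#' @return `rec`, invisibly, if valid; otherwise a validation error is thrown.
#' @export
validate_recording <- function(rec) {
  if (!inherits(rec, "multimodal_recording")) {
    stop_validation("not a multimodal_recording")
  }
  for (field in c("eeg", "emg", "fs", "eeg_channels", "emg_channels",
                  "subject_id", "recording_id")) {
    if (is.null(rec[[field]])) stop_validation("missing field '", field, "'")
  }
  if (!is.matrix(rec$eeg) || !is.matrix(rec$emg)) {
    stop_validation("eeg and emg must be channel x sample matrices")
  }
  if (ncol(rec$eeg) != ncol(rec$emg)) {
    stop_validation("eeg and emg sample counts differ (",
                    ncol(rec$eeg), " vs ", ncol(rec$emg), ")")
  }
  if (!is.numeric(rec$fs) || length(rec$fs) != 1 || rec$fs <= 0) {
    stop_validation("fs must be a single positive number")
  }
  if (length(rec$eeg_channels) != nrow(rec$eeg)) {
    stop_validation("eeg has ", nrow(rec$eeg), " rows but ",
                    length(rec$eeg_channels), " channel labels")
  }
  if (length(rec$emg_channels) != nrow(rec$emg)) {
    stop_validation("emg has ", nrow(rec$emg), " rows but ",
                    length(rec$emg_channels), " channel labels")
  }
  if (anyNA(rec$eeg) || anyNA(rec$emg) ||
      any(!is.finite(rec$eeg)) || any(!is.finite(rec$emg))) {
    stop_validation("signals contain NA/Inf values")
  }
  invisible(rec)
}

#' @export
print.multimodal_recording <- function(x, ...) {
  cat(sprintf(
    "<multimodal_recording %s/%s: %d EEG + %d EMG channels, %.1f s @ %g Hz>\n",
    x$subject_id, x$recording_id, nrow(x$eeg), nrow(x$emg),
    ncol(x$eeg) / x$fs, x$fs
  ))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a `multimodal_recording`.
#' @return length of the recording in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$eeg) / rec$fs

#' Write / read a recording container
#'
#' Single-file signal container with one array group per modality plus
#' metadata (sampling rate, channel labels, identifiers), serialized with R's
#' native format. The round trip is lossless for signal values and metadata.
#'
#' @param rec a valid `multimodal_recording`.
#' @param path file path (conventionally `.rds`).
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the validated `multimodal_recording`.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  saveRDS(unclass(rec), path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("cannot read recording container: ", path)
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("corrupt recording container at ", path, ": ", conditionMessage(e))
  })
  if (!is.list(obj) || is.null(obj$eeg) || is.null(obj$emg)) {
    stop_validation("container at ", path, " is missing an eeg/emg array group")
  }
  rec <- structure(obj, class = "multimodal_recording")
  validate_recording(rec)
  rec
}
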