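#' Preprocess the EEG stream of a recording
#'
#' Applies, in order: a zero-phase Butterworth band-pass (default 0.3-70 Hz,
#' overall order 4 via forward-backward filtering of a 2nd-order section pair),
#' a zero-phase 50 Hz notch (biquad, quality factor 30), and common-average
#' re-referencing (the cross-channel mean at each time point is subtracted).
#' The EMG stream is left untouched.
#'
#' @param rec a `multimodal_recording`.
#' @param low,high band-pass edges in Hz.
#' @param notch_hz notch center frequency in Hz; `NA` disables the notch.
#' @param notch_q notch quality factor (center frequency / -3 dB width).
#' @return the recording with filtered, re-referenced EEG.
#' @export
preprocess_eeg <- function(rec, low = 0.3, high = 70, notch_hz = 50,
                           notch_q = 30) {
  validate_recording(rec)
  if (rec$fs < 200 || high >= rec$fs / 2) {
    stop("sampling rate ", rec$fs, " Hz too low for a ", high,
         " Hz passband edge")
  }
  x <- bandpass_matrix(rec$eeg, rec$fs, low, high)
  if (!is.na(notch_hz)) x <- notch_matrix(x, rec$fs, notch_hz, notch_q)
  x <- sweep(x, 2, colMeans(x)) # common average reference per time point
  rec$eeg <- x
  validate_recording(rec)
  rec
}

#' Preprocess the EMG stream of a recording
#'
#' Zero-phase Butterworth band-pass of the EMG channels (default 5-500 Hz, the
#' surface-EMG band of the acquisition protocol). The EEG stream is untouched.
#' The upper edge must lie below the Nyquist frequency; with the default
#' 500 Hz edge this requires a sampling rate above 1000 Hz. Recordings
#' decimated for desk-scale experiments must pass a correspondingly lower
#' `high`.
#'
#' @param rec a `multimodal_recording`.
#' @param low,high band-pass edges in Hz.
#' @return the recording with filtered EMG.
#' @export
preprocess_emg <- function(rec, low = 5, high = 500) {
  validate_recording(rec)
  if (high >= rec$fs / 2) {
    stop("sampling rate ", rec$fs, " Hz too low for a ", high,
         " Hz passband edge (needs fs > ", 2 * high, ")")
  }
  rec$emg <- bandpass_matrix(rec$emg, rec$fs, low, high)
  validate_recording(rec)
  rec
}

#' Z-score every channel of a recording
#'
#' Normalizes each channel to zero mean and unit variance, per channel and per
#' recording (statistics are never pooled across recordings). Applied after
#' filtering.
#'
#' @param rec a `multimodal_recording`.
#' @return the normalized recording.
#' @export
zscore_recording <- function(rec) {
  validate_recording(rec)
  rec$eeg <- zscore_matrix(rec$eeg, rec$eeg_channels)
  rec$emg <- zscore_matrix(rec$emg, rec$emg_channels)
  rec
}

zscore_matrix <- function(x, labels) {
  mu <- rowMeans(x)
  centered <- x - mu
  s <- sqrt(rowSums(centered^2) / (ncol(x) - 1))
  flat <- which(s == 0 | !is.finite(s))
  if (length(flat) > 0) {
    stop("constant channel cannot be z-scored: ", labels[flat[1]])
  }
  centered / s
}

# 4th-order Butterworth band-pass implemented as a high-pass/low-pass cascade
# (numerically better conditioned than one transfer function when the lower
# edge sits far below Nyquist), applied forward-backward for zero phase.
bandpass_matrix <- function(x, fs, low, high) {
  hp <- signal::butter(4, low / (fs / 2), type = "high")
  lp <- signal::butter(4, high / (fs / 2), type = "low")
  t(apply(x, 1, function(ch) {
    signal::filtfilt(lp, signal::filtfilt(hp, ch))
  }))
}

# Standard audio-EQ biquad notch; r-signal ships no notch designer.
notch_coefficients <- function(fs, f0, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

notch_matrix <- function(x, fs, f0, q) {
  co <- notch_coefficients(fs, f0, q)
  t(apply(x, 1, function(ch) signal::filtfilt(co$b, co$a, ch)))
}
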