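#' Extract labeled analysis windows from an annotated recording
#'
#' Windowing follows the clinical protocol: fixed-length analysis windows
#' (default 1 s); ictal windows are sampled densely through every spasm event
#' on a 0.2-s start grid, while non-ictal windows are non-overlapping tiles
#' taken from interictal stretches at a safe distance from any event.
#'
#' Ictal enumeration: candidate starts are the grid points lying between
#' `onset` and `offset - window_s` (inclusive, in either order). For events at
#' least one window long this yields all fully-contained windows; for shorter
#' events it yields the windows that fully contain the event, so every event
#' - including ones as short as 0.4 s - contributes at least one window. Every
#' enumerated window has an overlap of at least `min(0.5 s, event duration)`
#' with its event.
#'
#' Non-ictal tiles start at whole multiples of `window_s` and are kept only if
#' their distance to every event boundary is at least `guard_s`, so the ictal
#' and non-ictal defining regions are mutually exclusive by construction.
#'
#' @param rec a preprocessed `multimodal_recording`.
#' @param ann an `event_annotations` object (events for other recordings are
#'   ignored).
#' @param window_s window length in seconds.
#' @param ictal_stride_s start grid of the dense ictal sampling, in seconds.
#' @param guard_s minimal distance (s) between a non-ictal tile and any event.
#' @return A `window_set`: EEG and EMG window arrays `[C, T_win, n]` plus a
#'   tibble `meta` with `label` (1 = ictal, 0 = non-ictal), `subject_id`,
#'   `recording_id` and `t_start`.
#' @export
extract_windows <- function(rec, ann, window_s = 1.0, ictal_stride_s = 0.2,
                            guard_s = 2.0) {
  validate_recording(rec)
  dur <- recording_duration(rec)
  if (window_s > dur) {
    stop("window (", window_s, " s) longer than recording (", dur, " s)")
  }
  ev <- events_for(ann, rec$recording_id)
  eps <- 1e-9

  ictal_starts <- numeric(0)
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      lo <- min(ev$onset_s[i], ev$offset_s[i] - window_s)
      hi <- max(ev$onset_s[i], ev$offset_s[i] - window_s)
      ks <- seq(ceiling((lo - eps) / ictal_stride_s),
                floor((hi + eps) / ictal_stride_s))
      starts <- ks * ictal_stride_s
      starts <- starts[starts >= -eps & starts <= dur - window_s + eps]
      ictal_starts <- c(ictal_starts, starts)
    }
    ictal_starts <- sort(unique(round(ictal_starts / ictal_stride_s)) *
                           ictal_stride_s)
  }

  tile_starts <- seq(0, dur - window_s + eps, by = window_s)
  if (nrow(ev) > 0) {
    keep <- vapply(tile_starts, function(s) {
      all(ev$onset_s >= s + window_s + guard_s - eps |
            ev$offset_s <= s - guard_s + eps)
    }, logical(1))
    tile_starts <- tile_starts[keep]
  }

  starts <- c(ictal_starts, tile_starts)
  labels <- c(rep(1L, length(ictal_starts)), rep(0L, length(tile_starts)))
  t_win <- round(window_s * rec$fs)
  n <- length(starts)
  eeg <- array(0, dim = c(nrow(rec$eeg), t_win, n))
  emg <- array(0, dim = c(nrow(rec$emg), t_win, n))
  for (i in seq_len(n)) {
    i0 <- floor(starts[i] * rec$fs + eps) # 0-based sample of the half-open span
    idx <- (i0 + 1):(i0 + t_win)
    eeg[, , i] <- rec$eeg[, idx, drop = FALSE]
    emg[, , i] <- rec$emg[, idx, drop = FALSE]
  }
  new_window_set(
    eeg, emg,
    tibble::tibble(
      label = labels,
      subject_id = rep(rec$subject_id, n),
      recording_id = rep(rec$recording_id, n),
      t_start = starts
    ),
    fs = rec$fs
  )
}

new_window_set <- function(eeg, emg, meta, fs) {
  structure(list(eeg = eeg, emg = emg, meta = meta, fs = fs),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(
    "<window_set: %d windows (%d ictal / %d non-ictal), %d EEG + %d EMG ch, T=%d @ %g Hz>\n",
    nrow(x$meta), sum(x$meta$label == 1), sum(x$meta$label == 0),
    dim(x$eeg)[1], dim(x$emg)[1], dim(x$eeg)[2], x$fs
  ))
  invisible(x)
}

#' Combine window sets from several recordings
#' @param ... `window_set` objects with identical geometry.
#' @return a single concatenated `window_set`.
#' @export
bind_windows <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "window_set")) {
    sets <- sets[[1]]
  }
  eeg <- do.call(c, lapply(sets, function(s) as.numeric(s$eeg)))
  emg <- do.call(c, lapply(sets, function(s) as.numeric(s$emg)))
  d1 <- dim(sets[[1]]$eeg)
  d2 <- dim(sets[[1]]$emg)
  n <- sum(vapply(sets, function(s) dim(s$eeg)[3], numeric(1)))
  new_window_set(
    array(eeg, dim = c(d1[1], d1[2], n)),
    array(emg, dim = c(d2[1], d2[2], n)),
    dplyr::bind_rows(lapply(sets, function(s) s$meta)),
    fs = sets[[1]]$fs
  )
}

#' Subset a window set by index
#' @param ws a `window_set`.
#' @param idx integer indices of the windows to keep.
#' @return the subsetted `window_set`.
#' @export
subset_windows <- function(ws, idx) {
  new_window_set(ws$eeg[, , idx, drop = FALSE], ws$emg[, , idx, drop = FALSE],
                 ws$meta[idx, , drop = FALSE], fs = ws$fs)
}

#' Balance the two classes by subsampling the majority class
#'
#' The minority class is kept untouched; the majority class is subsampled
#' uniformly at random with the given seed, so the result is deterministic
#' for a fixed seed.
#'
#' @param ws a `window_set` containing both classes.
#' @param seed integer seed for the subsampling draw.
#' @return a `window_set` with equal class counts.
#' @export
balance_classes <- function(ws, seed = 1L) {
  pos <- which(ws$meta$label == 1)
  neg <- which(ws$meta$label == 0)
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both classes must be present to balance (",
         length(pos), " ictal / ", length(neg), " non-ictal)")
  }
  n <- min(length(pos), length(neg))
  keep <- with_seed(seed, {
    if (length(pos) > n) pos <- sort(sample(pos, n))
    if (length(neg) > n) neg <- sort(sample(neg, n))
    sort(c(pos, neg))
  })
  subset_windows(ws, keep)
}

#' Split subjects into train / validation / test sets
#'
#' Subjects - never windows - are partitioned, so no subject contributes
#' windows to more than one set (no subject leakage). With 10 subjects and the
#' default 8:1:1 ratio the sets have sizes 8, 1 and 1.
#'
#' @param x a `window_set`, or a character vector of subject ids.
#' @param ratio length-3 numeric ratio for train:validation:test.
#' @param seed integer seed for the subject shuffle.
#' @return a `split_spec`: list with `train_subjects`, `val_subjects`,
#'   `test_subjects`, `ratio`, `seed`.
#' @export
subject_split <- function(x, ratio = c(8, 1, 1), seed = 1L) {
  subjects <- if (inherits(x, "window_set")) unique(x$meta$subject_id)
              else unique(as.character(x))
  n <- length(subjects)
  if (n < 3) stop("subject-wise split needs at least 3 subjects, got ", n)
  shuffled <- with_seed(seed, sample(subjects))
  n_test <- max(1L, round(n * ratio[3] / sum(ratio)))
  n_val <- max(1L, round(n * ratio[2] / sum(ratio)))
  if (n - n_val - n_test < 1) stop("ratio leaves no training subjects")
  structure(
    list(
      train_subjects = sort(shuffled[seq_len(n - n_val - n_test)]),
      val_subjects = sort(shuffled[(n - n_val - n_test + 1):(n - n_test)]),
      test_subjects = sort(shuffled[(n - n_test + 1):n]),
      ratio = ratio, seed = seed
    ),
    class = "split_spec"
  )
}

#' Partition a window set according to a subject split
#' @param ws a `window_set`.
#' @param split a `split_spec` from [subject_split()].
#' @return list of `window_set`s: `train`, `val`, `test`.
#' @export
split_windows <- function(ws, split) {
  pick <- function(subs) subset_windows(ws, which(ws$meta$subject_id %in% subs))
  list(
    train = pick(split$train_subjects),
    val = pick(split$val_subjects),
    test = pick(split$test_subjects)
  )
}
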