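# Seeded generator of synchronized EEG-EMG recordings with annotated spasm
# events. It emulates the statistical structure the detector exploits, not
# physiology: 1/f background with line noise, clustered events whose EEG
# signature is a high-voltage slow wave with superimposed spikes followed by
# electrodecremental attenuation, a lagged decaying EMG burst, and motion
# artifacts that contaminate both modalities (EMG much more specifically),
# so that EMG alone is an ambiguous witness of a spasm.

#' Synthetic cohort configuration
#'
#' Defaults describe the desk-scale study conditions: 10 subjects, one two-
#' minute recording each, 25 + 4 channels. Event morphology parameters are
#' expressed relative to the background RMS of the affected modality.
#'
#' @param n_subjects number of subjects.
#' @param recordings_per_subject recordings generated per subject.
#' @param recording_seconds length of each recording (s).
#' @param fs sampling rate (Hz).
#' @param n_eeg,n_emg channel counts.
#' @param event_rate spasm events per minute (events arrive in clusters).
#' @param duration_range_s range of event durations, drawn uniformly.
#' @param cluster list: `events_per_cluster_range` (integer range),
#'   `intra_cluster_gap_s` (range of gaps between clustered events).
#' @param eeg_event list: `slow_wave_hz_range`, `slow_gain` (slow-wave
#'   amplitude in background-RMS units), `spike_rate` (spikes/s during the
#'   slow-wave phase), `decrement_gain` (background attenuation factor in
#'   (0,1) after the spike), `decrement_seconds` (cap on the attenuation
#'   duration; the default equals the maximum event duration so the
#'   decrement spans the rest of the annotated event, as in clinical
#'   annotations where the attenuation is part of the marked event).
#' @param emg_event list: `lag_mean_s`, `lag_sd_s` (EMG burst onset lag after
#'   the EEG spike, truncated normal at 0), `burst_band_hz`, `decay_tau_s`
#'   (post-event decay constant; the tonic burst is sustained until the
#'   event offset), `burst_gain`.
#' @param noise list: `pink_exponent`, `line_hz`, `line_amp`,
#'   `artifact_rate` (motion artifacts per minute), `artifact_gain`.
#' @param seed base seed; all randomness derives from it.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_subjects = 10, recordings_per_subject = 1,
                         recording_seconds = 120, fs = 1024,
                         n_eeg = 25, n_emg = 4,
                         event_rate = 3,
                         duration_range_s = c(0.4, 9.2),
                         cluster = list(events_per_cluster_range = c(2L, 4L),
                                        intra_cluster_gap_s = c(2, 6)),
                         eeg_event = list(slow_wave_hz_range = c(1, 3),
                                          slow_gain = 3.5, spike_rate = 3,
                                          decrement_gain = 0.3,
                                          decrement_seconds = 9.2),
                         emg_event = list(lag_mean_s = 0.15, lag_sd_s = 0.05,
                                          burst_band_hz = c(20, 250),
                                          decay_tau_s = 0.4, burst_gain = 4),
                         noise = list(pink_exponent = 1, line_hz = 50,
                                      line_amp = 0.5, artifact_rate = 4,
                                      artifact_gain = 3.5),
                         seed = 1L) {
  stopifnot(duration_range_s[1] > 0,
            duration_range_s[2] < recording_seconds,
            eeg_event$decrement_gain > 0, eeg_event$decrement_gain < 1,
            emg_event$lag_mean_s >= 0)
  cfg <- list(
    n_subjects = n_subjects, recordings_per_subject = recordings_per_subject,
    recording_seconds = recording_seconds, fs = fs, n_eeg = n_eeg,
    n_emg = n_emg, event_rate = event_rate,
    duration_range_s = duration_range_s, cluster = cluster,
    eeg_event = eeg_event, emg_event = emg_event, noise = noise, seed = seed
  )
  cfg$emg_event$burst_band_hz[2] <- min(cfg$emg_event$burst_band_hz[2],
                                        0.45 * fs)
  structure(cfg, class = "synth_config")
}

#' Preset synthetic configurations
#'
#' `"paper-like"` uses the clinical geometry (1024 Hz, 10 subjects, two
#' minutes per recording, ~3 spasms/min as in the printed cohort statistics);
#' `"desk"` is the reduced preset used for end-to-end experiments: 256 Hz,
#' one-minute recordings, EMG burst band compressed below Nyquist.
#'
#' @param name `"paper-like"` or `"desk"`.
#' @param ... overrides passed on to [synth_config()].
#' @return a `synth_config`.
#' @export
synth_preset <- function(name = c("paper-like", "desk"), ...) {
  name <- match.arg(name)
  if (name == "paper-like") {
    synth_config(fs = 1024, ...)
  } else {
    synth_config(fs = 256, recording_seconds = 60,
                 emg_event = list(lag_mean_s = 0.15, lag_sd_s = 0.05,
                                  burst_band_hz = c(10, 100),
                                  decay_tau_s = 0.4, burst_gain = 4),
                 ...)
  }
}

# 1/f^beta noise via spectral shaping of white noise, unit variance.
pink_noise <- function(n, fs, exponent = 1) {
  w <- rnorm(n)
  W <- fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n
  shape <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(fft(W * shape, inverse = TRUE)) / n
  x / sd(x)
}

bandlimited_noise <- function(n, fs, band) {
  w <- rnorm(n)
  W <- fft(w)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n
  keep <- f >= band[1] & f <= band[2]
  x <- Re(fft(W * keep, inverse = TRUE)) / n
  x / sd(x)
}

# Non-overlapping event spans: clusters of events with short gaps, uniform
# durations, all snapped later to the 0.1-s annotation grid.
draw_event_spans <- function(cfg) {
  dur_total <- cfg$recording_seconds
  n_target <- round(cfg$event_rate * dur_total / 60)
  if (n_target == 0) return(tibble::tibble(onset = numeric(0),
                                           offset = numeric(0)))
  spans <- list()
  guard <- 1.0 # clear space between events so grid-snapped spans stay disjoint
  margin <- 2.0
  tries <- 0
  while (length(spans) < n_target && tries < 200) {
    tries <- tries + 1
    m <- sample(seq(cfg$cluster$events_per_cluster_range[1],
                    cfg$cluster$events_per_cluster_range[2]), 1)
    durs <- runif(m, cfg$duration_range_s[1], cfg$duration_range_s[2])
    gaps <- runif(m, cfg$cluster$intra_cluster_gap_s[1],
                  cfg$cluster$intra_cluster_gap_s[2])
    span_len <- sum(durs) + sum(gaps[-1])
    if (span_len > dur_total - 2 * margin) next
    start <- runif(1, margin, dur_total - margin - span_len)
    t <- start
    cand <- list()
    for (i in seq_len(m)) {
      cand[[i]] <- c(t, t + durs[i])
      t <- t + durs[i] + gaps[i]
    }
    ok <- all(vapply(cand, function(s) {
      all(vapply(spans, function(e) {
        s[2] + guard <= e[1] || s[1] >= e[2] + guard
      }, logical(1)))
    }, logical(1)))
    if (ok) spans <- c(spans, cand)
  }
  if (length(spans) == 0) {
    stop("failed to place any event span after bounded retries")
  }
  spans <- spans[seq_len(min(length(spans), n_target))]
  on <- vapply(spans, `[`, numeric(1), 1)
  off <- vapply(spans, `[`, numeric(1), 2)
  o <- order(on)
  # snap to the 0.1-s annotation grid, keeping at least the minimum duration
  on <- round(on[o], 1)
  off <- pmax(round(off[o], 1), on + 0.4)
  tibble::tibble(onset = on, offset = off)
}

smooth_gate <- function(n_total, i0, i1, fs, ramp_s = 0.05) {
  g <- numeric(n_total)
  i0 <- max(1, i0); i1 <- min(n_total, i1)
  if (i1 < i0) return(g)
  g[i0:i1] <- 1
  r <- max(2, round(ramp_s * fs))
  up <- seq(0, 1, length.out = r)
  a <- i0:min(i0 + r - 1, i1)
  g[a] <- g[a] * up[seq_along(a)]
  b <- max(i0, i1 - r + 1):i1
  g[b] <- g[b] * rev(up)[seq_along(b)]
  g
}

#' Generate one synthetic recording with annotations
#'
#' Fully determined by `(config$seed, subject_id, recording_id)`. Returns the
#' recording, its grid-snapped annotations, and a ground-truth detail table
#' (per-event spike time and EMG burst onset) used by calibration checks.
#'
#' @param config a [synth_config()].
#' @param subject_id,recording_id identifiers (also seed components).
#' @return list with `recording`, `annotations`, `detail`.
#' @export
generate_recording <- function(config, subject_id, recording_id = "r1") {
  seed <- derive_seed(config$seed, subject_id, recording_id)
  with_seed(seed, {
    fs <- config$fs
    n <- round(config$recording_seconds * fs)
    tgrid <- (seq_len(n) - 1) / fs
    ne <- config$n_eeg
    nm <- config$n_emg

    eeg <- matrix(0, ne, n)
    for (c in seq_len(ne)) eeg[c, ] <- pink_noise(n, fs, config$noise$pink_exponent)
    emg <- matrix(0, nm, n)
    for (c in seq_len(nm)) {
      emg[c, ] <- 0.8 * pink_noise(n, fs, 0.5) +
        0.6 * bandlimited_noise(n, fs, config$emg_event$burst_band_hz)
    }
    # line noise, common phase per modality
    ph <- runif(1, 0, 2 * pi)
    line <- sin(2 * pi * config$noise$line_hz * tgrid + ph)
    if (config$noise$line_hz < fs / 2) {
      eeg <- eeg + config$noise$line_amp *
        outer(runif(ne, 0.5, 1), line)
      emg <- emg + 0.5 * config$noise$line_amp * outer(runif(nm, 0.5, 1), line)
    }
    eeg_rms <- mean(sqrt(rowMeans(eeg^2)))
    emg_rms <- mean(sqrt(rowMeans(emg^2)))

    spans <- draw_event_spans(config)
    detail <- tibble::tibble(onset = numeric(0), offset = numeric(0),
                             t_spike = numeric(0), emg_onset = numeric(0))
    ev <- config$eeg_event
    mv <- config$emg_event
    for (i in seq_len(nrow(spans))) {
      on <- spans$onset[i]; off <- spans$offset[i]
      dur <- off - on
      slow_len <- max(0.3, 0.4 * dur)
      t_spike <- on + slow_len
      topo <- runif(ne, 0.3, 1)
      # high-voltage slow wave with superimposed spikes
      f0 <- runif(1, ev$slow_wave_hz_range[1], ev$slow_wave_hz_range[2])
      i0 <- floor(on * fs) + 1
      i1 <- min(n, floor(t_spike * fs))
      seg <- i0:i1
      env <- sin(pi * seq(0, 1, length.out = length(seg)))^2
      wave <- ev$slow_gain * eeg_rms *
        sin(2 * pi * f0 * (tgrid[seg] - on)) * env
      n_spk <- max(1, rpois(1, ev$spike_rate * slow_len))
      spk_t <- sort(runif(n_spk, on + 0.05, t_spike))
      spike_sig <- numeric(length(seg))
      for (ts in spk_t) {
        u <- (tgrid[seg] - ts) / 0.02
        spike_sig <- spike_sig - ev$slow_gain * eeg_rms * u * exp(-u^2 / 2)
      }
      eeg[, seg] <- eeg[, seg] + outer(topo, wave + spike_sig)
      # electrodecremental attenuation of the background from the spike to
      # the event offset (the attenuation is part of the annotated event)
      d0 <- i1 + 1
      d1 <- min(n, floor(min(off, t_spike + ev$decrement_seconds) * fs),
                floor(off * fs))
      if (d1 > d0) {
        g <- 1 - (1 - ev$decrement_gain) *
          smooth_gate(n, d0, d1, fs)[d0:d1]
        eeg[, d0:d1] <- eeg[, d0:d1] * rep(g, each = ne)
      }
      # lagged EMG burst: tonic contraction sustained to the event offset,
      # then an exponential release
      lag <- max(0, rnorm(1, mv$lag_mean_s, mv$lag_sd_s))
      b0 <- t_spike + lag
      hold <- max(0, off - b0)
      j0 <- floor(b0 * fs) + 1
      j1 <- min(n, floor((b0 + hold + 4 * mv$decay_tau_s) * fs),
                floor((off + 1.5) * fs))
      if (j1 > j0) {
        jj <- j0:j1
        tt <- tgrid[jj] - b0
        env <- pmin(1, tt / 0.03) * exp(-pmax(0, tt - hold) / mv$decay_tau_s)
        burst <- bandlimited_noise(length(jj), fs, mv$burst_band_hz) * env
        emg[, jj] <- emg[, jj] +
          outer(runif(nm, 0.5, 1), mv$burst_gain * emg_rms * burst)
      }
      detail <- dplyr::bind_rows(detail, tibble::tibble(
        onset = on, offset = off, t_spike = t_spike, emg_onset = b0
      ))
    }

    # motion artifacts in interictal stretches: EMG burst + EEG wobble,
    # without the spike/decrement sequence of a true spasm
    n_art <- round(config$noise$artifact_rate * config$recording_seconds / 60)
    placed <- 0
    tries <- 0
    while (placed < n_art && tries < 200) {
      tries <- tries + 1
      adur <- runif(1, 0.3, 1)
      a0 <- runif(1, 1, config$recording_seconds - 1 - adur)
      clear <- nrow(spans) == 0 ||
        all(spans$onset >= a0 + adur + 1 | spans$offset <= a0 - 1)
      if (!clear) next
      placed <- placed + 1
      k0 <- floor(a0 * fs) + 1
      k1 <- min(n, floor((a0 + adur) * fs))
      kk <- k0:k1
      tt <- tgrid[kk] - a0
      env <- pmin(1, tt / 0.03) * exp(-tt / (0.4 * adur))
      burst <- bandlimited_noise(length(kk), fs, mv$burst_band_hz) * env
      emg[, kk] <- emg[, kk] +
        outer(runif(nm, 0.5, 1), config$noise$artifact_gain * emg_rms * burst)
      wob <- sin(2 * pi * runif(1, 1, 3) * tt) *
        sin(pi * seq(0, 1, length.out = length(kk)))^2
      eeg[, kk] <- eeg[, kk] +
        outer(runif(ne, 0, 0.6), 1.5 * eeg_rms * wob)
    }

    rec <- multimodal_recording(
      eeg, emg, fs = fs,
      eeg_channels = paste0("EEG", seq_len(ne)),
      emg_channels = paste0("EMG", seq_len(nm)),
      subject_id = subject_id, recording_id = recording_id
    )
    ann <- event_annotations(tibble::tibble(
      recording_id = recording_id,
      onset_s = spans$onset, offset_s = spans$offset,
      label = rep("spasm", nrow(spans))
    ))
    list(recording = rec, annotations = ann, detail = detail)
  })
}

#' Simulate a full cohort in memory
#'
#' @param config a [synth_config()].
#' @return list with `recordings` (list of `multimodal_recording`),
#'   `annotations` (one `event_annotations` tibble over all recordings) and
#'   `details` (ground-truth event detail rows).
#' @export
simulate_cohort <- function(config) {
  recs <- list()
  ann_rows <- list()
  det_rows <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("sub%02d", s)
    for (r in seq_len(config$recordings_per_subject)) {
      rid <- sprintf("%s_r%d", sid, r)
      g <- generate_recording(config, sid, rid)
      recs[[rid]] <- g$recording
      ann_rows[[rid]] <- tibble::as_tibble(unclass_ann(g$annotations))
      det_rows[[rid]] <- dplyr::mutate(g$detail, recording_id = rid,
                                       subject_id = sid)
    }
  }
  ann <- dplyr::bind_rows(ann_rows)
  list(
    recordings = recs,
    annotations = if (nrow(ann) > 0) event_annotations(ann) else
      event_annotations(tibble::tibble(recording_id = character(0),
                                       onset_s = numeric(0),
                                       offset_s = numeric(0),
                                       label = character(0))),
    details = dplyr::bind_rows(det_rows)
  )
}

#' Write a synthetic dataset to disk
#'
#' One recording container per file, a single annotation CSV, and a JSON
#' manifest carrying the seed, a config hash and the subject list, so the
#' dataset can be regenerated and verified.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory (created if absent; existing files are an
#'   error).
#' @return the manifest, invisibly.
#' @export
generate_dataset <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  files <- character(0)
  for (rid in names(cohort$recordings)) {
    path <- file.path(out_dir, paste0(rid, ".rds"))
    if (file.exists(path)) stop("path collision: ", path)
    write_recording(cohort$recordings[[rid]], path)
    files <- c(files, basename(path))
  }
  ann_path <- file.path(out_dir, "annotations.csv")
  if (file.exists(ann_path)) stop("path collision: ", ann_path)
  write_annotations(cohort$annotations, ann_path)
  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    subjects = sort(unique(vapply(cohort$recordings,
                                  function(r) r$subject_id, character(1)))),
    recordings = files,
    fs = config$fs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
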