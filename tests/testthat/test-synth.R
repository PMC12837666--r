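test_that("generation is fully determined by the seed", {
  cfg <- tiny_synth_config(seed = 42)
  g1 <- generate_recording(cfg, "subA", "subA_r1")
  g2 <- generate_recording(cfg, "subA", "subA_r1")
  expect_identical(g1$recording$eeg, g2$recording$eeg)
  expect_identical(g1$recording$emg, g2$recording$emg)
  expect_identical(g1$annotations$onset_s, g2$annotations$onset_s)
  g3 <- generate_recording(tiny_synth_config(seed = 43), "subA", "subA_r1")
  expect_false(identical(g1$recording$eeg, g3$recording$eeg))
})

test_that("zero event rate gives pure background with empty annotations", {
  cfg <- tiny_synth_config(event_rate = 0)
  g <- generate_recording(cfg, "subA")
  expect_equal(nrow(g$annotations), 0)
  expect_true(all(is.finite(g$recording$eeg)))
})

test_that("all generated event spans are valid, snapped, in duration range", {
  cohort <- simulate_cohort(tiny_synth_config(seed = 7))
  ann <- cohort$annotations
  expect_gt(nrow(ann), 0)
  durs <- ann$offset_s - ann$onset_s
  expect_true(all(durs >= 0.4 - 1e-9 & durs <= 9.2 + 1e-9))
  grid_ok <- function(x) all(abs(x / 0.1 - round(x / 0.1)) < 1e-6)
  expect_true(grid_ok(ann$onset_s) && grid_ok(ann$offset_s))
  for (rid in unique(ann$recording_id)) {
    sub <- ann[ann$recording_id == rid, ]
    if (nrow(sub) > 1) {
      expect_true(all(sub$onset_s[-1] >= sub$offset_s[-nrow(sub)]))
    }
    dur <- spasmfusion::recording_duration(cohort$recordings[[rid]])
    expect_true(all(sub$offset_s <= dur + 1e-9))
  }
})

test_that("EMG burst onset lags the EEG spike by ~ lag_mean", {
  # threshold-crossing estimate of the EMG envelope onset over many events
  cfg <- synth_config(n_subjects = 10, recording_seconds = 120, fs = 256,
                      n_eeg = 4, n_emg = 2, event_rate = 6,
                      emg_event = list(lag_mean_s = 0.15, lag_sd_s = 0.05,
                                       burst_band_hz = c(10, 100),
                                       decay_tau_s = 0.4, burst_gain = 4),
                      seed = 99)
  lags <- c()
  for (s in 1:10) {
    g <- generate_recording(cfg, paste0("s", s))
    env <- abs(g$recording$emg[1, ])
    # robust background level (bursts would inflate a plain RMS)
    bg_rms <- median(env) * 1.4826
    for (i in seq_len(nrow(g$detail))) {
      t_spike <- g$detail$t_spike[i]
      i0 <- floor(t_spike * cfg$fs) + 1
      i1 <- min(length(env), i0 + 2 * cfg$fs)
      cross <- which(env[i0:i1] > 3 * bg_rms)[1]
      if (!is.na(cross)) lags <- c(lags, (cross - 1) / cfg$fs)
    }
  }
  expect_gte(length(lags), 100)
  expect_gte(median(lags), 0.10)
  expect_lte(median(lags), 0.20)
})

test_that("slow-wave gain dials up class separability monotonically", {
  # The gain scales the slow-wave/spike complex, so the dial is measured on
  # the windows overlapping the slow-wave phase (the decremental remainder
  # of each event separates the classes regardless of this gain).
  fisher <- function(gain) {
    vals <- c()
    labs <- c()
    for (r in 1:2) {
      cfg <- tiny_synth_config(recording_seconds = 90, seed = 5,
                               event_rate = 4)
      cfg$eeg_event$slow_gain <- gain
      g <- generate_recording(cfg, "subA", sprintf("subA_r%d", r))
      ws <- extract_windows(g$recording, g$annotations)
      slow_overlap <- function(t0) {
        max(vapply(seq_len(nrow(g$detail)), function(i) {
          max(0, min(t0 + 1, g$detail$t_spike[i]) -
                max(t0, g$detail$onset[i]))
        }, numeric(1)))
      }
      keep <- ws$meta$label == 0 |
        vapply(ws$meta$t_start, slow_overlap, numeric(1)) >= 0.5
      e <- apply(ws$eeg[, , keep, drop = FALSE], 3, function(w) {
        log(band_energy_profile(compute_scalogram(
          w, ws$fs, list(c(1, 4), c(4, 8), c(8, 16), c(16, 30)),
          scales_per_band = 2
        ))[1] + 1e-12)
      })
      vals <- c(vals, e)
      labs <- c(labs, ws$meta$label[keep])
    }
    a <- vals[labs == 1]
    b <- vals[labs == 0]
    (mean(a) - mean(b))^2 / (var(a) + var(b) + 1e-12)
  }
  f <- vapply(c(0.5, 2, 6), fisher, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("ictal windows carry time-locked EEG-EMG structure, tiles do not", {
  cfg <- tiny_synth_config(seed = 21, recording_seconds = 60, event_rate = 4)
  g <- generate_recording(cfg, "subA", "subA_r1")
  ws <- extract_windows(g$recording, g$annotations)
  env <- function(x) abs(x - mean(x))
  xcor_peak <- function(i) {
    e <- env(colMeans(ws$eeg[, , i]^2))
    m <- env(colMeans(ws$emg[, , i]^2))
    cc <- ccf(e, m, lag.max = ws$fs %/% 2, plot = FALSE)
    cc$lag[which.max(cc$acf)]
  }
  ict <- which(ws$meta$label == 1)
  peaks <- vapply(head(ict, 20), xcor_peak, numeric(1))
  # EEG power leads EMG power at a positive lag for a clear majority
  expect_gt(mean(peaks < 0), 0.5)
})

test_that("dataset writer emits containers, CSV and manifest; collisions error", {
  dir <- withr::local_tempdir()
  cfg <- tiny_synth_config(n_subjects = 3, seed = 13L)
  man <- generate_dataset(cfg, dir)
  expect_length(man$subjects, 3)
  expect_true(file.exists(file.path(dir, "annotations.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  rec <- read_recording(file.path(dir, man$recordings[1]))
  expect_s3_class(rec, "multimodal_recording")
  # regenerating with the stored seed reproduces the config hash
  man2 <- jsonlite::read_json(file.path(dir, "manifest.json"))
  cfg2 <- tiny_synth_config(n_subjects = 3, seed = as.integer(man2$seed))
  expect_equal(man2$config_hash, rlang::hash(unclass(cfg2)))
  expect_error(generate_dataset(cfg, dir), "collision")
})
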