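make_rec <- function(fs = 64, seconds = 30) {
  multimodal_recording(matrix(rnorm(2 * fs * seconds), 2),
                       matrix(rnorm(2 * fs * seconds), 2),
                       fs = fs, subject_id = "s1", recording_id = "r1")
}

ann_for <- function(spans) {
  event_annotations(tibble::tibble(
    recording_id = "r1",
    onset_s = vapply(spans, `[`, numeric(1), 1),
    offset_s = vapply(spans, `[`, numeric(1), 2),
    label = "spasm"
  ))
}

test_that("ictal enumeration matches the worked 1.6-s event example", {
  ws <- extract_windows(make_rec(), ann_for(list(c(10.0, 11.6))))
  ict <- ws$meta$t_start[ws$meta$label == 1]
  expect_equal(sort(ict), c(10.0, 10.2, 10.4, 10.6))
})

test_that("every enumerated ictal window overlaps its event by the rule", {
  spans <- list(c(3.0, 4.1), c(10.0, 17.3), c(20.0, 20.4))
  ws <- extract_windows(make_rec(), ann_for(spans))
  ict <- ws$meta$t_start[ws$meta$label == 1]
  overlap <- function(s, ev) max(0, min(s + 1, ev[2]) - max(s, ev[1]))
  for (s in ict) {
    best <- max(vapply(spans, function(ev) overlap(s, ev), numeric(1)))
    thresholds <- vapply(spans, function(ev) min(0.5, ev[2] - ev[1]),
                         numeric(1))
    expect_gte(best, min(thresholds))
  }
})

test_that("a 0.4-s event (the printed minimum) still yields ictal windows", {
  ws <- extract_windows(make_rec(), ann_for(list(c(3.0, 3.4))))
  ict <- ws$meta$t_start[ws$meta$label == 1]
  expect_gte(length(ict), 1)
  # each such window fully contains the event
  expect_true(all(ict <= 3.0 & ict + 1 >= 3.4))
})

test_that("without events all tiles are non-ictal and non-overlapping", {
  ws <- extract_windows(make_rec(), ann_for(list())[0, ])
  expect_equal(sum(ws$meta$label == 1), 0)
  starts <- sort(ws$meta$t_start)
  expect_true(all(diff(starts) >= 1 - 1e-9))
})

test_that("non-ictal tiles respect the guard margin (class exclusivity)", {
  spans <- list(c(8.0, 9.5), c(20.0, 21.0))
  ws <- extract_windows(make_rec(), ann_for(spans))
  tiles <- ws$meta$t_start[ws$meta$label == 0]
  for (s in tiles) {
    for (ev in spans) {
      dist <- max(ev[1] - (s + 1), s - ev[2])
      expect_gte(dist, 2 - 1e-9)
    }
  }
  # ictal and non-ictal start sets are disjoint
  expect_length(intersect(tiles, ws$meta$t_start[ws$meta$label == 1]), 0)
})

test_that("windows longer than the recording are rejected", {
  expect_error(extract_windows(make_rec(seconds = 2), ann_for(list()),
                               window_s = 5), "longer than")
})

test_that("class balancing equalizes counts deterministically", {
  ws <- extract_windows(make_rec(seconds = 30),
                        ann_for(list(c(5, 11), c(14, 19))))
  expect_gt(sum(ws$meta$label == 1), sum(ws$meta$label == 0))
  b1 <- balance_classes(ws, seed = 3)
  expect_equal(sum(b1$meta$label == 1), sum(b1$meta$label == 0))
  # minority class untouched
  expect_equal(sum(b1$meta$label == 0), sum(ws$meta$label == 0))
  b2 <- balance_classes(ws, seed = 3)
  expect_identical(b1$meta, b2$meta)
  b3 <- balance_classes(ws, seed = 4)
  expect_false(identical(b1$meta$t_start, b3$meta$t_start))
  only_pos <- subset_windows(ws, which(ws$meta$label == 1))
  expect_error(balance_classes(only_pos), "both classes")
})

test_that("subject split partitions subjects 8/1/1 without leakage", {
  subjects <- sprintf("sub%02d", 1:10)
  sp <- subject_split(subjects, seed = 5)
  expect_length(sp$train_subjects, 8)
  expect_length(sp$val_subjects, 1)
  expect_length(sp$test_subjects, 1)
  all_s <- c(sp$train_subjects, sp$val_subjects, sp$test_subjects)
  expect_setequal(all_s, subjects)
  expect_equal(anyDuplicated(all_s), 0)
  expect_identical(subject_split(subjects, seed = 5), sp)
  expect_error(subject_split(c("a", "b")), "at least 3")
})
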