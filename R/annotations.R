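#' Construct an event annotation set
#'
#' Spasm events are annotated as `[onset, offset)` spans in seconds at a fixed
#' temporal resolution (0.1 s in the clinical protocol). Events must be sorted
#' and non-overlapping; onsets and offsets are snapped to the resolution grid.
#'
#' @param events a data frame with columns `recording_id`, `onset_s`,
#'   `offset_s`, `label`.
#' @param resolution annotation grid in seconds (default 0.1).
#' @param snap snap onset/offset to the resolution grid (default `TRUE`);
#'   the maximal snap distance applied is recorded in the `snap_distance`
#'   attribute.
#' @return A tibble of class `event_annotations`, sorted by recording and
#'   onset, with attributes `resolution` and `snap_distance`.
#' @export
event_annotations <- function(events, resolution = 0.1, snap = TRUE) {
  ev <- tibble::as_tibble(events)
  needed <- c("recording_id", "onset_s", "offset_s", "label")
  missing_cols <- setdiff(needed, names(ev))
  if (length(missing_cols) > 0) {
    stop_validation("annotation table lacks columns: ",
                    paste(missing_cols, collapse = ", "))
  }
  ev$recording_id <- as.character(ev$recording_id)
  ev$label <- as.character(ev$label)
  snap_dist <- 0
  if (snap && nrow(ev) > 0) {
    snapped_on <- round(ev$onset_s / resolution) * resolution
    snapped_off <- round(ev$offset_s / resolution) * resolution
    snap_dist <- max(abs(c(snapped_on - ev$onset_s, snapped_off - ev$offset_s)))
    ev$onset_s <- snapped_on
    ev$offset_s <- snapped_off
  }
  bad <- which(ev$offset_s <= ev$onset_s)
  if (length(bad) > 0) {
    stop_validation("offset <= onset at row ", bad[1],
                    " (onset=", ev$onset_s[bad[1]],
                    ", offset=", ev$offset_s[bad[1]], ")")
  }
  if (any(ev$onset_s < 0)) stop_validation("negative onset")
  ev <- ev[order(ev$recording_id, ev$onset_s), , drop = FALSE]
  for (rid in unique(ev$recording_id)) {
    sub <- ev[ev$recording_id == rid, ]
    if (nrow(sub) > 1) {
      overlap <- which(sub$onset_s[-1] < sub$offset_s[-nrow(sub)])
      if (length(overlap) > 0) {
        stop_validation("overlapping events in recording ", rid,
                        " near t=", sub$onset_s[overlap[1] + 1], " s")
      }
    }
  }
  structure(ev, class = c("event_annotations", class(tibble::tibble())),
            resolution = resolution, snap_distance = snap_dist)
}

#' Read / write event annotations as CSV
#'
#' The on-disk format is a plain CSV with header
#' `recording_id,onset_s,offset_s,label`. Values are snapped to the 0.1-s
#' annotation grid on read; the applied snap distance is available as
#' `attr(x, "snap_distance")`.
#'
#' @param path CSV file path.
#' @param resolution annotation grid in seconds.
#' @return `read_annotations` returns an `event_annotations` tibble;
#'   `write_annotations` returns `path` invisibly.
#' @export
read_annotations <- function(path, resolution = 0.1) {
  if (!file.exists(path)) stop("cannot read annotations: ", path)
  ev <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  event_annotations(ev, resolution = resolution)
}

#' @rdname read_annotations
#' @param ann an `event_annotations` object.
#' @export
write_annotations <- function(ann, path) {
  readr::write_csv(tibble::as_tibble(unclass_ann(ann)), path, progress = FALSE)
  invisible(path)
}

unclass_ann <- function(ann) {
  out <- ann
  class(out) <- setdiff(class(out), "event_annotations")
  out[, c("recording_id", "onset_s", "offset_s", "label")]
}

# Events of one recording, as a plain tibble (possibly empty).
events_for <- function(ann, recording_id) {
  ann[ann$recording_id == recording_id, , drop = FALSE]
}
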