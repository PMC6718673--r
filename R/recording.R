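# The in-memory container for one imaging recording: long-format ROI traces
# (cells + cell-free background regions), the stimulus schedule, and the
# subject/pair/treatment labels carried through to the statistics.

#' Construct an imaging recording
#'
#' Bundles the ROI fluorescence time series of one subject/condition
#' recording with its stimulus-event schedule and metadata. Traces are held
#' in long format (`time_s`, `roi_id`, `roi_type`, `value`) with
#' `roi_type` either `"cell"` or `"background"`; background ROIs are drawn
#' over cell-free regions and their average is the background signal
#' subtracted before any response is quantified.
#'
#' @param traces Tibble with columns `time_s`, `roi_id`, `roi_type`
#'   (`"cell"` or `"background"`), `value`. All ROIs must share the same
#'   time grid; at least one background ROI is required.
#' @param events Tibble with columns `agent`, `onset_s`, `duration_s` and
#'   optionally `concentration`; agents must be unique and onsets ordered.
#' @param sampling_interval Seconds per frame.
#' @param subject_id,pair_id,role,treatment Metadata labels. `role` is one
#'   of `"ST"` (affected twin), `"HT"` (unaffected twin) or `"control"`;
#'   `treatment` typically `"pre"`/`"post"` (before/after drug exposure).
#' @return A `ca_recording` object.
#' @export
ca_recording <- function(traces, events, sampling_interval,
                         subject_id = NA_character_, pair_id = NA_character_,
                         role = NA_character_, treatment = NA_character_) {
  sampling_interval <- check_number(sampling_interval, "sampling_interval",
                                    lower = 1e-9)
  traces <- validate_trace_table(traces)
  events <- validate_event_table(events)
  if (!is.na(role) && !role %in% c("ST", "HT", "control")) {
    stop_twindff("`role` must be one of 'ST', 'HT', 'control'.", "config")
  }
  structure(
    list(traces = traces, events = events,
         sampling_interval = sampling_interval,
         subject_id = as.character(subject_id),
         pair_id = as.character(pair_id),
         role = as.character(role), treatment = as.character(treatment)),
    class = "ca_recording")
}

validate_trace_table <- function(traces) {
  required <- c("time_s", "roi_id", "roi_type", "value")
  missing <- setdiff(required, names(traces))
  if (length(missing) > 0) {
    stop_twindff(paste0("trace table is missing column(s): ",
                        paste(missing, collapse = ", ")), "structural")
  }
  traces <- tibble::as_tibble(traces)[required]
  if (!all(traces$roi_type %in% c("cell", "background"))) {
    stop_twindff("`roi_type` must be 'cell' or 'background'.", "structural")
  }
  if (!any(traces$roi_type == "background")) {
    stop_twindff("at least one background ROI is required.", "structural")
  }
  lens <- table(traces$roi_id)
  if (length(unique(as.integer(lens))) != 1L) {
    stop_twindff("all ROI series must have the same length.", "structural")
  }
  traces
}

validate_event_table <- function(events) {
  required <- c("agent", "onset_s", "duration_s")
  missing <- setdiff(required, names(events))
  if (length(missing) > 0) {
    stop_twindff(paste0("event table is missing column(s): ",
                        paste(missing, collapse = ", ")), "structural")
  }
  events <- tibble::as_tibble(events)
  if (!"concentration" %in% names(events)) {
    events$concentration <- NA_character_
  }
  if (anyDuplicated(events$agent)) {
    stop_twindff("stimulus agents must be unique within a recording.",
                 "structural")
  }
  if (is.unsorted(events$onset_s)) {
    stop_twindff("events must be ordered by onset.", "structural")
  }
  if (any(events$onset_s < 0) || any(events$duration_s <= 0)) {
    stop_twindff("event onsets must be >= 0 and durations > 0.", "structural")
  }
  events[c("agent", "onset_s", "duration_s", "concentration")]
}

#' @export
print.ca_recording <- function(x, ...) {
  n_cell <- length(unique(x$traces$roi_id[x$traces$roi_type == "cell"]))
  n_bg <- length(unique(x$traces$roi_id[x$traces$roi_type == "background"]))
  n_t <- length(unique(x$traces$time_s))
  cat(sprintf(
    "<ca_recording> subject %s (pair %s, %s, %s)\n  %d cell + %d background ROIs, %d frames @ %.3g s\n  events: %s\n",
    x$subject_id, x$pair_id, x$role, x$treatment,
    n_cell, n_bg, n_t, x$sampling_interval,
    paste(sprintf("%s@%gs", x$events$agent, x$events$onset_s),
          collapse = ", ")))
  invisible(x)
}

# time grid and per-ROI matrix views used internally
recording_times <- function(rec) {
  sort(unique(rec$traces$time_s))
}

recording_matrix <- function(rec, type) {
  tr <- rec$traces[rec$traces$roi_type == type, , drop = FALSE]
  tr <- tr[order(tr$roi_id, tr$time_s), , drop = FALSE]
  ids <- unique(tr$roi_id)
  n_t <- nrow(tr) / length(ids)
  matrix(tr$value, nrow = n_t, ncol = length(ids),
         dimnames = list(NULL, ids))
}

#' Subtract the background signal from every cell trace
#'
#' Averages the background (cell-free) ROI traces pointwise and subtracts
#' that mean series from each cell trace. Background traces are retained
#' unchanged for audit.
#'
#' @param recording A [ca_recording()].
#' @return A `ca_recording` with background-corrected cell traces.
#' @export
subtract_background <- function(recording) {
  stopifnot(inherits(recording, "ca_recording"))
  bg <- recording_matrix(recording, "background")
  bg_mean <- rowMeans(bg)
  times <- recording_times(recording)
  if (length(bg_mean) != length(times)) {
    stop_twindff("background and cell series lengths differ.", "structural")
  }
  idx <- match(recording$traces$time_s, times)
  is_cell <- recording$traces$roi_type == "cell"
  recording$traces$value[is_cell] <-
    recording$traces$value[is_cell] - bg_mean[idx[is_cell]]
  recording
}
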