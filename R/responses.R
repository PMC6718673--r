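# Per-cell response quantification: dF* = (f - f0)/f0 on the denoised,
# background-subtracted trace, followed by the two-stage ionomycin / KCl
# calibration and neuron classification.

#' Response window configuration
#'
#' The windows over which the response extrema are taken: `f` is the maximum
#' of the denoised trace in the `post_window` seconds following the stimulus
#' application, `f0` the minimum in the `pre_window` seconds before it.
#'
#' @param post_window Seconds after onset searched for the maximum
#'   (default 20).
#' @param pre_window Seconds before onset searched for the baseline minimum
#'   (default 50).
#' @return A `response_windows` list.
#' @export
response_windows <- function(post_window = 20, pre_window = 50) {
  structure(list(
    post_window = check_number(post_window, "post_window", lower = 1e-9),
    pre_window = check_number(pre_window, "pre_window", lower = 1e-9)),
    class = "response_windows")
}

#' Quantify one stimulus response on a denoised trace
#'
#' Computes the baseline-normalised response statistic
#' \eqn{dF^* = (f - f_0)/f_0}, where \eqn{f} is the maximum of the series in
#' the half-open window (onset, onset + post_window] and \eqn{f_0} the
#' minimum in the closed window \[onset - pre_window, onset\]. Including the
#' onset sample in the pre-window biases toward a conservative (lower)
#' baseline.
#'
#' @param series Denoised, background-subtracted numeric trace.
#' @param onset_s Stimulus onset in seconds.
#' @param windows A [response_windows()].
#' @param sampling_interval Seconds per frame; sample `i` sits at
#'   `(i - 1) * sampling_interval`.
#' @param agent Optional agent label carried into the result.
#' @return One-row tibble with `agent`, `f`, `f0`, `dF_star`.
#' @export
#' @examples
#' tr <- rep(1, 200); tr[101:110] <- 3
#' compute_response(tr, onset_s = 50, sampling_interval = 0.5)
compute_response <- function(series, onset_s, windows = response_windows(),
                             sampling_interval = 0.5, agent = NA_character_) {
  n <- length(series)
  t <- (seq_len(n) - 1) * sampling_interval
  if (onset_s - windows$pre_window < -1e-9 ||
      onset_s + windows$post_window > t[n] + 1e-9) {
    stop_twindff(sprintf(
      "response windows for onset %g s fall outside the recording (0-%g s).",
      onset_s, t[n]), "scheduling")
  }
  post <- t > onset_s & t <= onset_s + windows$post_window + 1e-9
  pre <- t >= onset_s - windows$pre_window - 1e-9 & t <= onset_s + 1e-9
  f <- max(series[post])
  f0 <- min(series[pre])
  if (f0 <= 0) {
    stop_twindff(sprintf(
      "baseline f0 = %g is not positive; dF* is undefined (check background subtraction).",
      f0), "calibration")
  }
  tibble::tibble(agent = agent, f = f, f0 = f0, dF_star = (f - f0) / f0)
}

#' Classify a cell as neuron or non-neuron from its KCl response
#'
#' Excitable neurons depolarise under KCl and produce a calcium transient;
#' non-neuronal cells do not, while both respond to the receptor-independent
#' ionophore ionomycin. A cell is called a neuron when its KCl response is at
#' least `min_ratio` of its ionomycin response.
#'
#' @param kcl_dfstar dF* for the KCl application.
#' @param iono_dfstar dF* for the ionomycin application; must be positive.
#' @param min_ratio Classification threshold on KCl/ionomycin (default 0.1).
#' @return Logical.
#' @export
classify_neuron <- function(kcl_dfstar, iono_dfstar, min_ratio = 0.1) {
  min_ratio <- check_number(min_ratio, "min_ratio", lower = 0)
  if (any(!is.finite(iono_dfstar)) || any(iono_dfstar <= 0)) {
    stop_twindff("ionomycin dF* must be positive to classify cells.",
                 "calibration")
  }
  kcl_dfstar / iono_dfstar >= min_ratio
}

#' Two-stage calibration of a cell's raw responses
#'
#' First divides every raw dF* by the cell's ionomycin dF* (per-cell maximal
#' calcium response), then divides the agonist responses by the
#' ionomycin-calibrated KCl response. Algebraically the ionomycin response
#' cancels from the final agonist ratios, leaving raw agonist / raw KCl; both
#' stages are still reported for audit and because the intermediate
#' ionomycin-calibrated values are of interest in their own right.
#'
#' @param raw Named numeric vector of raw dF* values, one per agent; must
#'   contain `"KCl"` and `"ionomycin"` with positive values.
#' @return Tibble with one row per agent and columns `agent`, `dF_star`,
#'   `iono_calibrated`, `final`. `final` is `NA` for the two calibrators.
#' @export
#' @examples
#' calibrate_cell(c(GABA = 0.3, GluGlyNoMg = 0.5, KCl = 1, ionomycin = 2))
calibrate_cell <- function(raw) {
  if (is.null(names(raw)) || any(!nzchar(names(raw)))) {
    stop_twindff("`raw` must be a named vector of per-agent dF* values.",
                 "structural")
  }
  if (!all(c("KCl", "ionomycin") %in% names(raw))) {
    stop_twindff("calibration requires both a KCl and an ionomycin response.",
                 "incomplete_protocol")
  }
  if (!is.finite(raw[["ionomycin"]]) || raw[["ionomycin"]] <= 0) {
    stop_twindff("ionomycin dF* must be positive for calibration.",
                 "calibration")
  }
  if (!is.finite(raw[["KCl"]]) || raw[["KCl"]] <= 0) {
    stop_twindff("KCl dF* must be positive for calibration.", "calibration")
  }
  iono_cal <- raw / raw[["ionomycin"]]
  final <- iono_cal / iono_cal[["KCl"]]
  final[c("KCl", "ionomycin")] <- NA_real_
  tibble::tibble(agent = names(raw),
                 dF_star = unname(raw),
                 iono_calibrated = unname(iono_cal),
                 final = unname(final))
}

#' Quantify and calibrate every cell of a recording
#'
#' The full per-recording pipeline: background subtraction, wavelet
#' denoising of each cell trace, dF* quantification for every stimulus
#' event, neuron classification from the KCl/ionomycin ratio, and the
#' two-stage calibration.
#'
#' @param recording A [ca_recording()] whose events include `"KCl"` and
#'   `"ionomycin"`.
#' @param denoise_cfg A [denoise_config()].
#' @param windows A [response_windows()].
#' @param min_neuron_ratio Threshold passed to [classify_neuron()].
#' @return Tibble with one row per cell x agent: `subject_id`, `pair_id`,
#'   `role`, `treatment`, `roi_id`, `is_neuron`, `agent`, `dF_star`,
#'   `iono_calibrated`, `final`.
#' @export
process_recording <- function(recording, denoise_cfg = denoise_config(),
                              windows = response_windows(),
                              min_neuron_ratio = 0.1) {
  stopifnot(inherits(recording, "ca_recording"))
  if (!all(c("KCl", "ionomycin") %in% recording$events$agent)) {
    stop_twindff("recording must include KCl and ionomycin applications.",
                 "incomplete_protocol")
  }
  rec <- subtract_background(recording)
  cells <- recording_matrix(rec, "cell")
  events <- rec$events
  per_cell <- purrr::map(colnames(cells), function(roi) {
    den <- denoise(cells[, roi], denoise_cfg)
    raw <- vapply(seq_len(nrow(events)), function(i) {
      compute_response(den, events$onset_s[i], windows,
                       rec$sampling_interval, events$agent[i])$dF_star
    }, numeric(1))
    names(raw) <- events$agent
    is_neuron <- classify_neuron(raw[["KCl"]], raw[["ionomycin"]],
                                 min_neuron_ratio)
    out <- if (is_neuron) {
      calibrate_cell(raw)
    } else {
      # non-neurons have no meaningful KCl calibrator; they are excluded
      # from the twin contrast, so only the raw and ionomycin-calibrated
      # stages are reported
      tibble::tibble(agent = names(raw), dF_star = unname(raw),
                     iono_calibrated = unname(raw / raw[["ionomycin"]]),
                     final = NA_real_)
    }
    out$roi_id <- roi
    out$is_neuron <- is_neuron
    out
  })
  res <- dplyr::bind_rows(per_cell)
  tibble::tibble(subject_id = rec$subject_id, pair_id = rec$pair_id,
                 role = rec$role, treatment = rec$treatment,
                 roi_id = res$roi_id, is_neuron = res$is_neuron,
                 agent = res$agent, dF_star = res$dF_star,
                 iono_calibrated = res$iono_calibrated, final = res$final)
}

#' Process a collection of recordings into one response table
#'
#' @param recordings List of [ca_recording()] objects (e.g. from
#'   [simulate_twin_cohort()]).
#' @inheritParams process_recording
#' @return Row-bound tibble of [process_recording()] results.
#' @export
process_cohort <- function(recordings, denoise_cfg = denoise_config(),
                           windows = response_windows(),
                           min_neuron_ratio = 0.1) {
  purrr::map_dfr(recordings, process_recording, denoise_cfg = denoise_cfg,
                 windows = windows, min_neuron_ratio = min_neuron_ratio)
}
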