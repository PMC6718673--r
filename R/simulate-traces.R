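# Synthetic single-recording generator: stimulus-locked calcium transients
# on a noisy baseline, plus cell-free background ROIs. The generator's
# defaults define the simulated study conditions used throughout the tests.

#' Trace simulation configuration
#'
#' Parameters of the synthetic fluorescence model. Each cell trace is
#' `baseline_level + background_level` plus, at every stimulus onset, a
#' difference-of-exponentials transient scaled to the configured amplitude,
#' plus white Gaussian noise; background ROIs carry `background_level` plus
#' noise only. Non-neuron cells respond to ionomycin (receptor independent)
#' but not to KCl or the agonists.
#'
#' @param sampling_interval Seconds per frame (default 0.5, i.e. 2 Hz).
#' @param duration Recording length in seconds.
#' @param baseline_level Resting cell fluorescence above background (a.u.).
#' @param noise_sd SD of the additive white noise (a.u.).
#' @param background_level Cell-free background fluorescence (a.u.).
#' @param n_background_rois Number of background ROIs (default 3).
#' @param transient_rise,transient_decay Rise and decay time constants of
#'   the transient kernel in seconds; rise must be shorter than decay.
#' @param stimulus_amplitudes Named vector mapping agent to peak transient
#'   amplitude in a.u. The defaults put KCl between the agonists and the
#'   receptor-independent ionomycin maximum.
#' @param neuron_fraction Fraction of cells that are neurons.
#' @param outlier_fraction Fraction of cells whose agonist responses are
#'   inflated by `outlier_scale` (aberrant cells for the MAD filter to
#'   catch).
#' @param outlier_scale Multiplier applied to outlier cells' agonist
#'   amplitudes.
#' @return A `trace_sim_config` list.
#' @export
trace_sim_config <- function(sampling_interval = 0.5, duration = 340,
                             baseline_level = 1, noise_sd = 0.05,
                             background_level = 0.2, n_background_rois = 3L,
                             transient_rise = 0.5, transient_decay = 4,
                             stimulus_amplitudes = c(KCl = 1, GABA = 0.6,
                                                     GluGlyNoMg = 0.8,
                                                     ionomycin = 2),
                             neuron_fraction = 0.8, outlier_fraction = 0,
                             outlier_scale = 5) {
  cfg <- list(
    sampling_interval = check_number(sampling_interval, "sampling_interval",
                                     lower = 1e-6),
    duration = check_number(duration, "duration", lower = 1e-6),
    baseline_level = check_number(baseline_level, "baseline_level"),
    noise_sd = check_number(noise_sd, "noise_sd", lower = 0),
    background_level = check_number(background_level, "background_level"),
    n_background_rois = check_count(n_background_rois, "n_background_rois",
                                    lower = 1L),
    transient_rise = check_number(transient_rise, "transient_rise",
                                  lower = 1e-6),
    transient_decay = check_number(transient_decay, "transient_decay",
                                   lower = 1e-6),
    stimulus_amplitudes = stimulus_amplitudes,
    neuron_fraction = check_number(neuron_fraction, "neuron_fraction",
                                   lower = 0, upper = 1),
    outlier_fraction = check_number(outlier_fraction, "outlier_fraction",
                                    lower = 0, upper = 1),
    outlier_scale = check_number(outlier_scale, "outlier_scale", lower = 0))
  if (is.null(names(stimulus_amplitudes)) ||
      any(!nzchar(names(stimulus_amplitudes)))) {
    stop_twindff("`stimulus_amplitudes` must be a named vector.", "config")
  }
  if (any(stimulus_amplitudes < 0)) {
    stop_twindff("stimulus amplitudes must be >= 0.", "config")
  }
  if (cfg$transient_rise >= cfg$transient_decay) {
    stop_twindff("`transient_rise` must be shorter than `transient_decay`.",
                 "config")
  }
  structure(cfg, class = "trace_sim_config")
}

#' Default stimulus schedule
#'
#' A schedule of brief (2 s) bath applications mirroring a standard
#' receptor-profiling protocol: GABA, then glutamate + glycine in Mg-free
#' solution (NMDA-receptor biased), then KCl depolarisation to identify
#' excitable neurons, and finally the calcium ionophore ionomycin as the
#' per-cell maximal-response calibrator at the end of the recording. Onsets
#' are spaced so that every event has a full pre-window baseline and
#' post-window response period.
#'
#' @param agents Agents to include, in application order.
#' @param first_onset Onset of the first application in seconds.
#' @param spacing Seconds between consecutive onsets.
#' @param application_s Application duration in seconds (default 2).
#' @return Tibble with columns `agent`, `onset_s`, `duration_s`,
#'   `concentration`.
#' @export
default_stimulus_schedule <- function(agents = c("GABA", "GluGlyNoMg",
                                                 "KCl", "ionomycin"),
                                      first_onset = 60, spacing = 80,
                                      application_s = 2) {
  conc <- c(GABA = "100 uM", GluGly = "100 uM + 10 uM glycine",
            GluGlyNoMg = "100 uM + 10 uM glycine, Mg-free",
            KCl = "30 mM", ionomycin = "10 uM")
  tibble::tibble(
    agent = agents,
    onset_s = first_onset + spacing * (seq_along(agents) - 1),
    duration_s = application_s,
    concentration = unname(conc[agents]))
}

# difference-of-exponentials kernel evaluated at offsets s >= 0 from the
# onset, normalised so its maximum over the sampled support is exactly 1
transient_kernel <- function(s, rise, decay) {
  k <- exp(-s / decay) - exp(-s / rise)
  m <- max(k)
  if (m <= 0) {
    stop_twindff("transient kernel has no positive sample; event too close to the end of the recording.",
                 "scheduling")
  }
  k / m
}

#' Simulate one imaging recording
#'
#' Generates `n_cells` cell ROI traces plus background ROI traces under a
#' [trace_sim_config()]. A rounded `neuron_fraction` share of cells are
#' neurons; non-neurons receive zero KCl/agonist amplitude but the full
#' ionomycin amplitude. A rounded `outlier_fraction` share of cells have
#' their agonist amplitudes multiplied by `outlier_scale`. Identical
#' configuration and seed give bitwise-identical recordings.
#'
#' @param cfg A [trace_sim_config()].
#' @param events Stimulus schedule tibble (see
#'   [default_stimulus_schedule()]). Every event must leave at least a full
#'   pre-window before and post-window after its onset.
#' @param n_cells Number of cell ROIs.
#' @param seed Integer seed; the generator never touches global RNG state.
#' @param windows [response_windows()] used only to validate the schedule.
#' @param subject_id,pair_id,role,treatment Metadata stamped on the
#'   recording.
#' @param amplitude_overrides Optional `n_cells` x agents numeric matrix
#'   (columns named by agent) replacing the per-cell amplitudes before the
#'   non-neuron zeroing and outlier scaling are applied; used by
#'   [simulate_twin_cohort()] to encode pair-level effects.
#' @return A [ca_recording()]. Attributes `neuron_idx` and `outlier_idx`
#'   record the ground-truth cell labels.
#' @export
#' @examples
#' rec <- simulate_recording(n_cells = 4, seed = 1)
#' rec
simulate_recording <- function(cfg = trace_sim_config(),
                               events = default_stimulus_schedule(),
                               n_cells = 20L, seed = 1L,
                               windows = response_windows(),
                               subject_id = "S1", pair_id = NA_character_,
                               role = NA_character_,
                               treatment = NA_character_,
                               amplitude_overrides = NULL) {
  stopifnot(inherits(cfg, "trace_sim_config"))
  n_cells <- check_count(n_cells, "n_cells", lower = 1L)
  events <- validate_event_table(events)
  t <- seq(0, cfg$duration, by = cfg$sampling_interval)
  n_t <- length(t)
  if (any(events$onset_s - windows$pre_window < -1e-9) ||
      any(events$onset_s + windows$post_window > cfg$duration + 1e-9)) {
    stop_twindff(sprintf(
      "every event needs >= %g s before and >= %g s after its onset within the %g s recording.",
      windows$pre_window, windows$post_window, cfg$duration), "scheduling")
  }
  missing_amp <- setdiff(events$agent, names(cfg$stimulus_amplitudes))
  if (length(missing_amp) > 0) {
    stop_twindff(paste0("no amplitude configured for agent(s): ",
                        paste(missing_amp, collapse = ", ")), "config")
  }

  agents <- events$agent
  agonists <- setdiff(agents, c("KCl", "ionomycin"))
  with_seed(seed, {
    neuron_idx <- sort(sample.int(n_cells, round(cfg$neuron_fraction * n_cells)))
    outlier_idx <- sort(sample.int(n_cells, round(cfg$outlier_fraction * n_cells)))

    # per-cell amplitude matrix
    amp <- matrix(rep(cfg$stimulus_amplitudes[agents], each = n_cells),
                  nrow = n_cells, dimnames = list(NULL, agents))
    if (!is.null(amplitude_overrides)) {
      if (!is.matrix(amplitude_overrides) ||
          nrow(amplitude_overrides) != n_cells ||
          is.null(colnames(amplitude_overrides))) {
        stop_twindff("`amplitude_overrides` must be an n_cells x agents matrix with agent column names.",
                     "config")
      }
      for (a in intersect(colnames(amplitude_overrides), agents)) {
        amp[, a] <- amplitude_overrides[, a]
      }
    }
    non_neuron <- setdiff(seq_len(n_cells), neuron_idx)
    amp[non_neuron, setdiff(agents, "ionomycin")] <- 0
    if (length(agonists) > 0 && length(outlier_idx) > 0) {
      amp[outlier_idx, agonists] <- amp[outlier_idx, agonists] * cfg$outlier_scale
    }

    # deterministic transient template per event
    signal <- matrix(0, nrow = n_t, ncol = n_cells)
    for (i in seq_len(nrow(events))) {
      idx <- which(t >= events$onset_s[i])
      k <- transient_kernel(t[idx] - events$onset_s[i],
                            cfg$transient_rise, cfg$transient_decay)
      signal[idx, ] <- signal[idx, ] + outer(k, amp[, agents[i]])
    }

    cell_values <- cfg$baseline_level + cfg$background_level + signal +
      if (cfg$noise_sd > 0) {
        matrix(rnorm(n_t * n_cells, sd = cfg$noise_sd), nrow = n_t)
      } else 0
    bg_values <- cfg$background_level +
      if (cfg$noise_sd > 0) {
        matrix(rnorm(n_t * cfg$n_background_rois, sd = cfg$noise_sd),
               nrow = n_t)
      } else {
        matrix(0, nrow = n_t, ncol = cfg$n_background_rois)
      }

    cell_ids <- sprintf("cell_%03d", seq_len(n_cells))
    bg_ids <- sprintf("bg_%d", seq_len(cfg$n_background_rois))
    traces <- tibble::tibble(
      time_s = rep(t, n_cells + cfg$n_background_rois),
      roi_id = rep(c(cell_ids, bg_ids), each = n_t),
      roi_type = rep(c("cell", "background"),
                     times = c(n_cells * n_t, cfg$n_background_rois * n_t)),
      value = c(as.numeric(cell_values), as.numeric(bg_values)))

    rec <- ca_recording(traces, events, cfg$sampling_interval,
                        subject_id = subject_id, pair_id = pair_id,
                        role = role, treatment = treatment)
    attr(rec, "neuron_idx") <- neuron_idx
    attr(rec, "outlier_idx") <- outlier_idx
    rec
  })
}
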