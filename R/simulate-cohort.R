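# Twin-cohort generators with known ground truth. The generative model is
# the one the two-level test assumes: a pair-level true ST-HT difference
# delta_i ~ N(delta, tau^2) on the calibrated-response scale, plus
# independent cell-level noise within each subject.

#' Twin cohort design
#'
#' Ground-truth parameters of a simulated discordant-twin cohort on the
#' calibrated-response scale (the scale of the `final` column produced by
#' [process_recording()], i.e. agonist dF* divided by the two calibrators).
#'
#' @param n_pairs Number of discordant monozygotic pairs.
#' @param cells_per_subject Cells recorded per subject and treatment.
#' @param true_pair_effect Mean true ST - HT difference \eqn{\delta} of the
#'   targeted agent's calibrated response under the `pre` condition.
#' @param post_effect Mean ST - HT difference under the `post` condition
#'   (default 0: the drug abolishes the difference).
#' @param between_pair_sd SD \eqn{\tau} of the pair-level effect around its
#'   mean (shared between conditions within a pair).
#' @param within_subject_cell_sd SD of the cell-level noise around the
#'   subject's expected response.
#' @param baseline_response Expected calibrated response of an unaffected
#'   (HT) cell.
#' @param agent Targeted stimulus agent the effect acts on.
#' @param treatment_labels Treatment conditions to generate.
#' @param group_label Free-text cohort label (e.g. `"TRS"` or `"non-TRS"`).
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_pairs = 5L, cells_per_subject = 50L,
                          true_pair_effect = 0.3, post_effect = 0,
                          between_pair_sd = 0.1,
                          within_subject_cell_sd = 0.2,
                          baseline_response = 0.6, agent = "GABA",
                          treatment_labels = c("pre", "post"),
                          group_label = "TRS") {
  structure(list(
    n_pairs = check_count(n_pairs, "n_pairs", lower = 1L),
    cells_per_subject = check_count(cells_per_subject, "cells_per_subject",
                                    lower = 2L),
    true_pair_effect = check_number(true_pair_effect, "true_pair_effect"),
    post_effect = check_number(post_effect, "post_effect"),
    between_pair_sd = check_number(between_pair_sd, "between_pair_sd",
                                   lower = 0),
    within_subject_cell_sd = check_number(within_subject_cell_sd,
                                          "within_subject_cell_sd",
                                          lower = 0),
    baseline_response = check_number(baseline_response, "baseline_response"),
    agent = as.character(agent),
    treatment_labels = as.character(treatment_labels),
    group_label = as.character(group_label)),
    class = "cohort_design")
}

# pair-level random effects shared by both generators
draw_pair_effects <- function(design) {
  u <- rnorm(design$n_pairs, 0, design$between_pair_sd)
  tibble::tibble(
    pair_id = sprintf("pair_%02d", seq_len(design$n_pairs)),
    pair_deviation = u,
    effect_pre = design$true_pair_effect + u,
    effect_post = design$post_effect + u)
}

#' Simulate cell-level calibrated responses for a twin cohort
#'
#' Draws responses directly on the calibrated scale, skipping trace
#' synthesis and denoising: for pair \eqn{i} a pair effect
#' \eqn{\delta_i \sim N(\delta, \tau^2)} shifts the affected (ST) twin's
#' expected response, and each cell adds independent
#' \eqn{N(0, \sigma_w^2)} noise. This is the fast generator used for the
#' type-I-error, bias and coverage simulations; [simulate_twin_cohort()]
#' realises the identical model as full fluorescence recordings.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed.
#' @return Tibble shaped like the [process_recording()] response table
#'   (columns `pair_id`, `subject_id`, `role`, `treatment`, `roi_id`,
#'   `is_neuron`, `agent`, `final`), with the ground-truth pair effects in
#'   attribute `"ground_truth"`.
#' @export
simulate_cohort_responses <- function(design = cohort_design(), seed = 1L) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(seed, {
    gt <- draw_pair_effects(design)
    n_cells <- design$cells_per_subject
    grid <- tidyr::expand_grid(
      pair_id = gt$pair_id,
      role = c("ST", "HT"),
      treatment = design$treatment_labels)
    grid$effect <- ifelse(
      grid$role == "ST",
      ifelse(grid$treatment == "post",
             gt$effect_post[match(grid$pair_id, gt$pair_id)],
             gt$effect_pre[match(grid$pair_id, gt$pair_id)]),
      0)
    n_groups <- nrow(grid)
    mu <- design$baseline_response + rep(grid$effect, each = n_cells)
    values <- mu + rnorm(n_groups * n_cells, 0, design$within_subject_cell_sd)
    out <- tibble::tibble(
      pair_id = rep(grid$pair_id, each = n_cells),
      subject_id = paste0(rep(grid$pair_id, each = n_cells), "_",
                          rep(grid$role, each = n_cells)),
      role = rep(grid$role, each = n_cells),
      treatment = rep(grid$treatment, each = n_cells),
      roi_id = sprintf("cell_%03d", rep(seq_len(n_cells), n_groups)),
      is_neuron = TRUE,
      agent = design$agent,
      final = values)
    attr(out, "ground_truth") <- gt
    out
  })
}

#' Simulate a twin cohort as full imaging recordings
#'
#' Realises the [cohort_design()] model at the fluorescence-trace level:
#' for every pair, role and treatment one recording is generated with
#' [simulate_recording()], where each cell's targeted-agent transient
#' amplitude encodes its intended calibrated response (amplitude = response
#' x KCl amplitude, since the final calibrated ratio for an agonist reduces
#' to agonist amplitude / KCl amplitude). Cell responses that would require
#' a negative amplitude are clipped to zero with a warning; under the
#' default design this is rare.
#'
#' @param design A [cohort_design()].
#' @param trace_cfg A [trace_sim_config()]; its `stimulus_amplitudes` must
#'   cover the scheduled agents and its noise/outlier settings apply to
#'   every recording.
#' @param seed Integer seed.
#' @param events Stimulus schedule (must include the design's targeted
#'   agent plus KCl and ionomycin).
#' @return List of [ca_recording()] objects with pair/role/treatment
#'   metadata, ground truth in attribute `"ground_truth"`.
#' @export
simulate_twin_cohort <- function(design = cohort_design(),
                                 trace_cfg = trace_sim_config(), seed = 1L,
                                 events = default_stimulus_schedule()) {
  stopifnot(inherits(design, "cohort_design"),
            inherits(trace_cfg, "trace_sim_config"))
  events <- validate_event_table(events)
  needed <- unique(c(design$agent, "KCl", "ionomycin"))
  if (!all(needed %in% events$agent)) {
    stop_twindff(paste0("stimulus schedule must include: ",
                        paste(needed, collapse = ", ")), "config")
  }
  kcl_amp <- trace_cfg$stimulus_amplitudes[["KCl"]]
  grid <- tidyr::expand_grid(
    pair_id = sprintf("pair_%02d", seq_len(design$n_pairs)),
    role = c("ST", "HT"),
    treatment = design$treatment_labels)

  sim <- with_seed(seed, {
    gt <- draw_pair_effects(design)
    rec_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
    responses <- lapply(seq_len(nrow(grid)), function(i) {
      eff <- if (grid$role[i] == "HT") 0 else if (grid$treatment[i] == "post")
        gt$effect_post[match(grid$pair_id[i], gt$pair_id)] else
        gt$effect_pre[match(grid$pair_id[i], gt$pair_id)]
      design$baseline_response + eff +
        rnorm(design$cells_per_subject, 0, design$within_subject_cell_sd)
    })
    list(gt = gt, rec_seeds = rec_seeds, responses = responses)
  })

  n_clipped <- 0L
  recs <- lapply(seq_len(nrow(grid)), function(i) {
    target <- sim$responses[[i]]
    n_clipped <<- n_clipped + sum(target < 0)
    overrides <- matrix(pmax(target, 0) * kcl_amp,
                        ncol = 1, dimnames = list(NULL, design$agent))
    simulate_recording(
      cfg = trace_cfg, events = events,
      n_cells = design$cells_per_subject, seed = sim$rec_seeds[i],
      subject_id = paste0(grid$pair_id[i], "_", grid$role[i]),
      pair_id = grid$pair_id[i], role = grid$role[i],
      treatment = grid$treatment[i], amplitude_overrides = overrides)
  })
  if (n_clipped > 0) {
    warn(sprintf("%d cell response(s) were negative and clipped to zero amplitude.",
                 n_clipped))
  }
  attr(recs, "ground_truth") <- sim$gt
  attr(recs, "design") <- design
  recs
}

#' Replicate the twin-contrast test over simulated cohorts
#'
#' Monte-Carlo harness for operating characteristics of the two-level test:
#' generates `n_sim` cohorts with [simulate_cohort_responses()] and runs
#' [twin_contrast_test()] on each, collecting the pooled results. Used for
#' type-I error, bias and coverage studies.
#'
#' @param design A [cohort_design()].
#' @param n_sim Number of replicate cohorts.
#' @param seed Integer seed; per-replicate seeds are drawn from it.
#' @param treatment Treatment stratum to test (default `"pre"`).
#' @param outlier_cfg An [outlier_config()] passed through to the test.
#' @return Tibble with one row per replicate: `sim`, `estimate`, `std.error`,
#'   `tau2`, `Q`, `statistic`, `p.value`, `k`.
#' @export
twin_power_sim <- function(design = cohort_design(), n_sim = 200L,
                           seed = 1L, treatment = "pre",
                           outlier_cfg = outlier_config()) {
  n_sim <- check_count(n_sim, "n_sim", lower = 1L)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_sim))
  one <- function(i) {
    resp <- simulate_cohort_responses(design, seed = seeds[i])
    fit <- twin_contrast_test(resp, agent = design$agent,
                              treatment = treatment,
                              outlier_cfg = outlier_cfg)
    glance(fit)
  }
  out <- purrr::map_dfr(seq_len(n_sim), one)
  out$sim <- seq_len(n_sim)
  dplyr::relocate(out, "sim")
}
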