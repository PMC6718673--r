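# The two-level random-effects twin contrast. Level one pools the cells of
# each subject (after robust outlier removal) into a mean and the variance
# of that mean; level two pools the per-pair ST-HT differences with
# inverse-variance weights and a DerSimonian-Laird between-pair variance.

#' Outlier filter configuration
#'
#' A measurement is flagged as an outlier when it lies more than
#' `k * consistency * MAD` from the median, where MAD is the median absolute
#' deviation from the median and `consistency = 1.4826` rescales the MAD to
#' estimate a Gaussian standard deviation.
#'
#' @param k Multiplier on the consistency-corrected MAD (default 3).
#' @param consistency Gaussian consistency factor (default 1.4826).
#' @return An `outlier_config` list.
#' @export
outlier_config <- function(k = 3, consistency = 1.4826) {
  structure(list(k = check_number(k, "k", lower = 1e-9),
                 consistency = check_number(consistency, "consistency",
                                            lower = 1e-9)),
            class = "outlier_config")
}

#' Remove MAD outliers from a vector of responses
#'
#' Keeps values within `k * consistency * MAD` of the median. When the MAD
#' is zero (at least half the values identical) the threshold degenerates
#' and all values are kept.
#'
#' @param values Numeric vector, at least one finite value.
#' @param cfg An [outlier_config()].
#' @return The retained values, in input order.
#' @export
#' @examples
#' remove_outliers(c(1, 2, 3, 100))
remove_outliers <- function(values, cfg = outlier_config()) {
  if (length(values) < 1L || !is.numeric(values)) {
    stop_twindff("`values` must be a non-empty numeric vector.", "structural")
  }
  if (any(!is.finite(values))) {
    stop_twindff("`values` contains non-finite entries.", "structural")
  }
  med <- median(values)
  mad_raw <- median(abs(values - med))
  if (mad_raw == 0) return(values)
  values[abs(values - med) <= cfg$k * cfg$consistency * mad_raw]
}

#' Summarise one subject's cells into a mean and its variance
#'
#' The first-level sufficient statistics: the arithmetic mean of the
#' subject's (outlier-filtered) cell responses and the variance of that
#' mean, i.e. the unbiased sample variance divided by the number of cells
#' (so its square root is the SE of the average).
#'
#' @param values Numeric vector of at least two responses.
#' @return One-row tibble with `mean`, `var_of_mean`, `n_cells`.
#' @export
#' @examples
#' summarize_subject(c(1, 2, 3))  # mean 2, var_of_mean 1/3
summarize_subject <- function(values) {
  if (!is.numeric(values) || length(values) < 2L) {
    stop_twindff("at least two cell responses are required to estimate a subject mean and its variance.",
                 "insufficient_cells")
  }
  tibble::tibble(mean = mean(values),
                 var_of_mean = var(values) / length(values),
                 n_cells = length(values))
}

#' Per-pair ST-HT differences from subject summaries
#'
#' For every pair computes `y = mean(ST) - mean(HT)` and its variance
#' `v = var_of_mean(ST) + var_of_mean(HT)` (the first-level variances sum
#' because the twins' cells are independent samples).
#'
#' @param summaries Tibble with columns `pair_id`, `role` (`"ST"`/`"HT"`),
#'   `mean`, `var_of_mean` and optionally `n_cells`; exactly one row per
#'   pair and role.
#' @return Tibble with one row per complete pair: `pair_id`, `y`, `v`,
#'   `se`, and cell counts when available.
#' @export
pair_differences <- function(summaries) {
  required <- c("pair_id", "role", "mean", "var_of_mean")
  missing <- setdiff(required, names(summaries))
  if (length(missing) > 0) {
    stop_twindff(paste0("`summaries` is missing column(s): ",
                        paste(missing, collapse = ", ")), "pairing")
  }
  if (!all(summaries$role %in% c("ST", "HT"))) {
    stop_twindff("`role` must be 'ST' or 'HT'.", "pairing")
  }
  if (anyDuplicated(summaries[c("pair_id", "role")])) {
    stop_twindff("more than one summary per pair and role; group keys are ambiguous.",
                 "pairing")
  }
  has_n <- "n_cells" %in% names(summaries)
  wide <- tidyr::pivot_wider(
    summaries, id_cols = "pair_id", names_from = "role",
    values_from = if (has_n) c("mean", "var_of_mean", "n_cells")
                  else c("mean", "var_of_mean"))
  value_cols <- c("mean_ST", "mean_HT", "var_of_mean_ST", "var_of_mean_HT",
                  if (has_n) c("n_cells_ST", "n_cells_HT"))
  for (col in setdiff(value_cols, names(wide))) wide[[col]] <- NA_real_
  complete <- !is.na(wide$mean_ST) & !is.na(wide$mean_HT)
  if (!all(complete)) {
    warn(sprintf("dropping %d incomplete pair(s): %s",
                 sum(!complete),
                 paste(wide$pair_id[!complete], collapse = ", ")))
    wide <- wide[complete, , drop = FALSE]
  }
  out <- tibble::tibble(
    pair_id = wide$pair_id,
    y = wide$mean_ST - wide$mean_HT,
    v = wide$var_of_mean_ST + wide$var_of_mean_HT)
  out$se <- sqrt(out$v)
  if (has_n) {
    out$n_st <- wide$n_cells_ST
    out$n_ht <- wide$n_cells_HT
  }
  out
}

#' DerSimonian-Laird random-effects pooling
#'
#' Inverse-variance-weighted random-effects meta-analysis of per-pair
#' differences with the DerSimonian-Laird moment estimator of the
#' between-pair variance: with fixed-effect weights \eqn{w_i = 1/v_i},
#' \eqn{Q = \sum w_i (y_i - \bar y_w)^2} and
#' \eqn{\tau^2 = \max(0, (Q - (k-1)) / (\sum w_i - \sum w_i^2 / \sum w_i))};
#' the pooled estimate then re-weights by \eqn{1/(v_i + \tau^2)}. The
#' p-value is the two-sided standard-normal tail of `pooled / se`.
#'
#' @param y Numeric vector of pair differences.
#' @param v Their variances (all positive), same length.
#' @return A `dl_pool` object with elements `pooled`, `se`, `tau2`, `Q`,
#'   `z`, `p`, `k`, plus the inputs. Supports [glance()], [tidy()] and
#'   `print()`.
#' @export
#' @examples
#' dersimonian_laird(c(0, 2), c(1, 1))  # Q = 2, tau2 = 1, pooled = 1
dersimonian_laird <- function(y, v) {
  if (length(y) < 1L || length(y) != length(v)) {
    stop_twindff("`y` and `v` must be non-empty vectors of equal length.",
                 "structural")
  }
  if (any(!is.finite(y)) || any(!is.finite(v))) {
    stop_twindff("`y` and `v` must be finite.", "structural")
  }
  if (any(v <= 0)) {
    stop_twindff("all variances must be positive for inverse-variance weighting.",
                 "weighting")
  }
  k <- length(y)
  w <- 1 / v
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  tau2 <- if (k == 1L) 0 else {
    denom <- sum(w) - sum(w^2) / sum(w)
    max(0, (Q - (k - 1)) / denom)
  }
  wstar <- 1 / (v + tau2)
  pooled <- sum(wstar * y) / sum(wstar)
  se <- 1 / sqrt(sum(wstar))
  z <- pooled / se
  structure(list(pooled = pooled, se = se, tau2 = tau2, Q = Q, z = z,
                 p = 2 * pnorm(-abs(z)), k = k, y = y, v = v),
            class = "dl_pool")
}

#' @export
print.dl_pool <- function(x, ...) {
  cat(sprintf(
    "DerSimonian-Laird pooled estimate over %d pair(s)\n  pooled %.4g (SE %.4g), tau2 %.4g, Q %.4g, Z %.3f, p %.3g\n",
    x$k, x$pooled, x$se, x$tau2, x$Q, x$z, x$p))
  invisible(x)
}

#' @rdname dersimonian_laird
#' @param x A `dl_pool` object.
#' @param ... Unused.
#' @export
glance.dl_pool <- function(x, ...) {
  tibble::tibble(estimate = x$pooled, std.error = x$se, tau2 = x$tau2,
                 Q = x$Q, statistic = x$z, p.value = x$p, k = x$k)
}

#' @rdname dersimonian_laird
#' @export
tidy.dl_pool <- function(x, ...) {
  tibble::tibble(term = paste0("pair_", seq_len(x$k)), y = x$y, v = x$v,
                 se = sqrt(x$v), weight = (1 / (x$v + x$tau2)) /
                   sum(1 / (x$v + x$tau2)))
}

#' Two-level random-effects twin contrast
#'
#' The full hierarchical test of whether affected (ST) twins' calibrated
#' responses differ on average from their unaffected (HT) co-twins for one
#' agent and treatment condition. Level one removes MAD outliers within
#' each subject's cells and forms each subject's mean and the variance of
#' the mean; level two takes the per-pair ST-HT differences (variances
#' summed) and pools them with [dersimonian_laird()].
#'
#' @param responses Response tibble (from [process_recording()],
#'   [process_cohort()] or [simulate_cohort_responses()]) with columns
#'   `pair_id`, `role`, `treatment`, `agent`, the value column, and
#'   optionally `is_neuron` (non-neurons are excluded when present).
#' @param agent Agent to test.
#' @param treatment Treatment stratum to test.
#' @param value Name of the response column (default `"final"`, the fully
#'   calibrated response).
#' @param outlier_cfg An [outlier_config()].
#' @param min_cells Minimum cells a subject must retain after filtering
#'   (default 2); subjects below it are dropped with a warning.
#' @param var_floor Lower bound imposed on a zero variance of the mean (all
#'   retained cells identical), so the pair keeps a finite weight; applied
#'   with a warning.
#' @return A `twin_contrast` object: `pairs` (the level-one tibble of
#'   per-pair differences), `pooled` (the [dersimonian_laird()] fit),
#'   `agent`, `treatment`, `n_outliers_removed`. Supports [tidy()],
#'   [glance()], `print()` and [autoplot()].
#' @export
twin_contrast_test <- function(responses, agent, treatment,
                               value = "final",
                               outlier_cfg = outlier_config(),
                               min_cells = 2L, var_floor = 1e-12) {
  for (col in c("pair_id", "role", "treatment", "agent", value)) {
    if (!col %in% names(responses)) {
      stop_twindff(sprintf("`responses` is missing column '%s'.", col),
                   "structural")
    }
  }
  df <- responses[responses$agent == agent &
                    responses$treatment == treatment, , drop = FALSE]
  if ("is_neuron" %in% names(df)) df <- df[df$is_neuron, , drop = FALSE]
  df <- df[is.finite(df[[value]]), , drop = FALSE]
  if (nrow(df) == 0) {
    stop_twindff(sprintf("no responses for agent '%s', treatment '%s'.",
                         agent, treatment), "structural")
  }

  groups <- split(df[[value]], paste(df$pair_id, df$role, sep = "\r"))
  n_removed <- 0L
  rows <- lapply(names(groups), function(key) {
    vals <- groups[[key]]
    kept <- remove_outliers(vals, outlier_cfg)
    n_removed <<- n_removed + (length(vals) - length(kept))
    if (length(kept) < min_cells) return(NULL)
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    s <- summarize_subject(kept)
    tibble::tibble(pair_id = parts[1], role = parts[2],
                   mean = s$mean, var_of_mean = s$var_of_mean,
                   n_cells = s$n_cells)
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped)) {
    warn(sprintf("%d subject group(s) dropped for having fewer than %d cells after outlier removal.",
                 sum(dropped), min_cells))
  }
  summaries <- dplyr::bind_rows(rows[!dropped])
  if (nrow(summaries) == 0) {
    stop_twindff("no subject retained enough cells to summarise.",
                 "insufficient_cells")
  }
  if (any(summaries$var_of_mean < var_floor)) {
    warn("a subject's variance of the mean is (near) zero; flooring it to keep a finite weight.")
    summaries$var_of_mean <- pmax(summaries$var_of_mean, var_floor)
  }
  pairs <- pair_differences(summaries)
  if (nrow(pairs) == 0) {
    stop_twindff("no complete ST/HT pair available for this stratum.",
                 "pairing")
  }
  pooled <- dersimonian_laird(pairs$y, pairs$v)
  structure(list(pairs = pairs, pooled = pooled, agent = agent,
                 treatment = treatment, value = value,
                 n_outliers_removed = n_removed),
            class = "twin_contrast")
}

#' @export
print.twin_contrast <- function(x, ...) {
  cat(sprintf("Twin contrast: %s (%s), %d pair(s), %d outlier cell(s) removed\n",
              x$agent, x$treatment, x$pooled$k, x$n_outliers_removed))
  print(x$pooled)
  invisible(x)
}

#' @rdname twin_contrast_test
#' @param x A `twin_contrast` object.
#' @param ... Unused.
#' @export
tidy.twin_contrast <- function(x, ...) {
  out <- x$pairs
  out$agent <- x$agent
  out$treatment <- x$treatment
  dplyr::relocate(out, "agent", "treatment")
}

#' @rdname twin_contrast_test
#' @export
glance.twin_contrast <- function(x, ...) {
  out <- glance(x$pooled)
  out$agent <- x$agent
  out$treatment <- x$treatment
  out$n_outliers_removed <- x$n_outliers_removed
  dplyr::relocate(out, "agent", "treatment")
}
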