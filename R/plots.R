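# ggplot2 views of recordings, twin contrasts and overlap results.

#' Plot the traces of a recording
#'
#' Cell traces with stimulus onsets marked; background ROIs drawn dashed.
#'
#' @param recording A [ca_recording()].
#' @param rois Optional ROI ids to restrict to.
#' @param max_cells Cap on the number of cell traces drawn (default 12).
#' @return A ggplot object.
#' @export
plot_recording <- function(recording, rois = NULL, max_cells = 12L) {
  stopifnot(inherits(recording, "ca_recording"))
  tr <- recording$traces
  if (!is.null(rois)) {
    tr <- tr[tr$roi_id %in% rois, , drop = FALSE]
  } else {
    cells <- unique(tr$roi_id[tr$roi_type == "cell"])
    keep <- c(head(cells, max_cells),
              unique(tr$roi_id[tr$roi_type == "background"]))
    tr <- tr[tr$roi_id %in% keep, , drop = FALSE]
  }
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$value,
                                   group = .data$roi_id,
                                   colour = .data$roi_type,
                                   linetype = .data$roi_type)) +
    ggplot2::geom_line(linewidth = 0.3, alpha = 0.8) +
    ggplot2::geom_vline(data = recording$events,
                        ggplot2::aes(xintercept = .data$onset_s),
                        colour = "grey40", linetype = "dotted") +
    ggplot2::annotate("text", x = recording$events$onset_s, y = Inf,
                      label = recording$events$agent, vjust = 1.2,
                      size = 3) +
    ggplot2::scale_colour_manual(values = c(cell = "#1b6ca8",
                                            background = "grey60")) +
    ggplot2::scale_linetype_manual(values = c(cell = "solid",
                                              background = "dashed")) +
    ggplot2::labs(x = "time (s)", y = "fluorescence (a.u.)",
                  title = sprintf("%s (%s, %s)", recording$subject_id,
                                  recording$role, recording$treatment)) +
    ggplot2::theme_minimal()
}

#' Forest-style plot of a twin contrast
#'
#' Shows both levels of the hierarchical analysis: each pair's mean ST-HT
#' difference with +/- 1 SE whiskers, and the pooled random-effects
#' estimate as a horizontal line with its +/- 1 SE band.
#'
#' @param object A `twin_contrast` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twin_contrast <- function(object, ...) {
  pairs <- object$pairs
  pooled <- object$pooled
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$pair_id, y = .data$y)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = pooled$pooled - pooled$se,
                      ymax = pooled$pooled + pooled$se,
                      fill = "cyan3", alpha = 0.2) +
    ggplot2::geom_hline(yintercept = pooled$pooled, colour = "cyan3",
                        linewidth = 1) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$y - .data$se,
                                          ymax = .data$y + .data$se,
                                          colour = .data$pair_id),
                             show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "ST - HT calibrated response",
                  title = sprintf("%s (%s): pooled %.3g, Z = %.2f, p = %.3g",
                                  object$agent, object$treatment,
                                  pooled$pooled, pooled$z, pooled$p)) +
    ggplot2::theme_minimal()
}

#' Bar plot of an overlap enrichment result
#'
#' Observed overlap proportion of the gene list against the baseline
#' proportion of the reference set in the universe.
#'
#' @param object An [overlap_enrichment()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.overlap_enrichment <- function(object, ...) {
  df <- tibble::tibble(
    group = factor(c("gene list", "universe baseline"),
                   levels = c("gene list", "universe baseline")),
    proportion = c(object$proportion, object$baseline_proportion))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$proportion,
                                   fill = .data$group)) +
    ggplot2::geom_col(show.legend = FALSE, width = 0.6) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%",
                                                             100 * x)) +
    ggplot2::labs(x = NULL, y = "share in reference set",
                  title = sprintf("%d/%d overlap (%.1f%%), Fisher p = %.2g",
                                  object$n_overlap, object$n_list,
                                  100 * object$proportion,
                                  object$fisher_p)) +
    ggplot2::theme_minimal()
}
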