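# Differential-expression filtering and gene-set overlap enrichment: the
# sex-specificity analysis operates on plain DEG tables (gene_id, log2fc,
# padj) and character-vector gene sets.

#' Filter a DEG table by the standard cutoffs
#'
#' A gene is differentially expressed when its adjusted p-value is strictly
#' below `alpha` and its absolute log2 fold change is at least `lfc_min`
#' ("at least twofold" = one-fold log2 change, read inclusively).
#'
#' @param deg_table Data frame with columns `gene_id`, `log2fc`, `padj`;
#'   gene ids must be unique.
#' @param lfc_min Minimum absolute log2 fold change (default 1).
#' @param alpha Adjusted p-value cutoff, strict (default 0.05).
#' @return Character vector of gene ids passing the filter.
#' @export
#' @examples
#' tbl <- tibble::tibble(gene_id = c("a", "b"), log2fc = c(1, 2),
#'                       padj = c(0.04, 0.05))
#' filter_degs(tbl)  # "a": padj 0.05 is not < 0.05
filter_degs <- function(deg_table, lfc_min = 1, alpha = 0.05) {
  deg_table <- validate_deg_table(deg_table)
  lfc_min <- check_number(lfc_min, "lfc_min", lower = 0)
  alpha <- check_number(alpha, "alpha", lower = 0, upper = 1)
  keep <- deg_table$padj < alpha & abs(deg_table$log2fc) >= lfc_min
  deg_table$gene_id[keep]
}

validate_deg_table <- function(deg_table) {
  required <- c("gene_id", "log2fc", "padj")
  missing <- setdiff(required, names(deg_table))
  if (length(missing) > 0) {
    stop_twindff(paste0("DEG table is missing column(s): ",
                        paste(missing, collapse = ", ")), "structural")
  }
  if (anyDuplicated(deg_table$gene_id)) {
    stop_twindff("DEG table contains duplicated gene ids; records are ambiguous.",
                 "structural")
  }
  if (any(!is.finite(deg_table$log2fc))) {
    stop_twindff("`log2fc` must be finite.", "structural")
  }
  if (any(deg_table$padj <= 0 | deg_table$padj > 1)) {
    stop_twindff("`padj` must lie in (0, 1].", "structural")
  }
  tibble::as_tibble(deg_table)
}

#' Linear fold change from a log2 fold change
#'
#' @param lfc Log2 fold change(s).
#' @return `2^lfc`. E.g. `fold_from_log2(7.94)` is about 246 and
#'   `fold_from_log2(0.379)` about 1.30 (a 30% change).
#' @export
fold_from_log2 <- function(lfc) {
  if (any(!is.finite(lfc))) {
    stop_twindff("`lfc` must be finite.", "structural")
  }
  2^lfc
}

#' Signed gene-ranking score
#'
#' The score used to order genes for running-sum enrichment analyses:
#' log2 fold change multiplied by \eqn{-\log_{10}} of the adjusted p-value,
#' so strongly up-regulated significant genes rank at the top and strongly
#' down-regulated ones at the bottom.
#'
#' @param log2fc Log2 fold change(s).
#' @param padj Adjusted p-value(s) in (0, 1]; floor zeros upstream, since a
#'   zero gives an infinite score.
#' @return Numeric score(s), vectorised.
#' @export
#' @examples
#' rank_score(2, 0.01)   # 4
#' rank_score(-1, 0.1)   # -1
rank_score <- function(log2fc, padj) {
  if (any(!is.finite(log2fc))) {
    stop_twindff("`log2fc` must be finite.", "structural")
  }
  if (any(padj <= 0 | padj > 1)) {
    stop_twindff("`padj` must lie in (0, 1]; floor zero p-values before scoring.",
                 "structural")
  }
  log2fc * (-log10(padj))
}

#' Overlap enrichment of a gene list against a reference set
#'
#' Counts how many genes of `genes` fall in `reference`, and tests whether
#' that proportion exceeds the reference set's share of the universe using
#' Fisher's exact test and Pearson's chi-squared test on the 2x2 table
#' (in list / not in list) x (in reference / not in reference).
#'
#' @param genes Character vector, the gene list of interest (e.g. illness
#'   DEGs); must be contained in `universe`.
#' @param reference Character vector, the annotated set (e.g. sex-specific
#'   genes); must be contained in `universe`.
#' @param universe Character vector of all detectable genes.
#' @param alternative Sidedness of Fisher's test (default two-sided).
#' @param correct Apply Yates continuity correction to the chi-squared test
#'   (default `FALSE`, plain Pearson).
#' @param ref_margin With `"excluded"` (default) the reference margin of
#'   the table excludes the list itself (the standard 2x2 partition); with
#'   `"full"` the second row is the whole-universe split
#'   (reference vs rest), comparing the list proportion against the
#'   unadjusted universe proportion.
#' @return One-row tibble with counts, proportions, `fisher_p`, `chi2_p`
#'   and the sample odds ratio.
#' @export
overlap_enrichment <- function(genes, reference, universe,
                               alternative = c("two.sided", "greater",
                                               "less"),
                               correct = FALSE,
                               ref_margin = c("excluded", "full")) {
  alternative <- match.arg(alternative)
  ref_margin <- match.arg(ref_margin)
  genes <- unique(as.character(genes))
  reference <- unique(as.character(reference))
  universe <- unique(as.character(universe))
  if (!all(genes %in% universe)) {
    stop_twindff("`genes` must be contained in `universe`.", "containment")
  }
  if (!all(reference %in% universe)) {
    stop_twindff("`reference` must be contained in `universe`.",
                 "containment")
  }
  n <- length(universe)
  m <- length(genes)
  big_k <- length(reference)
  k <- length(intersect(genes, reference))
  if (m == 0) {
    stop_twindff("`genes` is empty; no overlap proportion is defined.",
                 "structural")
  }
  tab <- if (ref_margin == "excluded") {
    matrix(c(k, m - k, big_k - k, n - m - (big_k - k)), nrow = 2,
           byrow = TRUE)
  } else {
    matrix(c(k, m - k, big_k, n - big_k), nrow = 2, byrow = TRUE)
  }
  fisher_p <- stats::fisher.test(tab, alternative = alternative)$p.value
  chi2_p <- suppressWarnings(
    stats::chisq.test(tab, correct = correct)$p.value)
  odds_ratio <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  structure(tibble::tibble(
    n_list = m, n_overlap = k, proportion = k / m,
    universe_size = n, universe_hits = big_k,
    baseline_proportion = big_k / n,
    fisher_p = fisher_p, chi2_p = chi2_p, odds_ratio = odds_ratio),
    class = c("overlap_enrichment", "tbl_df", "tbl", "data.frame"))
}

#' Venn region counts for 2-4 gene sets
#'
#' Exact counts of every non-empty membership region (genes in a given
#' combination of sets and in none of the others). Region counts sum to the
#' size of the union.
#'
#' @param sets Named list of 2-4 character vectors.
#' @return Tibble with columns `region` (set names joined by `&`),
#'   `n_sets_in` and `count`, one row per membership combination.
#' @export
#' @examples
#' venn_counts(list(A = c("x", "y", "z"), B = c("z", "w")))
venn_counts <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L || length(sets) > 4L) {
    stop_twindff("`sets` must be a list of 2 to 4 gene sets.", "structural")
  }
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop_twindff("`sets` must be named.", "structural")
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, ,
                                                                 drop = FALSE]
  names(combos) <- names(sets)
  counts <- apply(combos, 1, function(inset) {
    sum(apply(member, 1, function(row) all(row == inset)))
  })
  tibble::tibble(
    region = apply(combos, 1, function(inset) {
      paste(names(sets)[as.logical(inset)], collapse = "&")
    }),
    n_sets_in = rowSums(combos),
    count = as.integer(counts))
}
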