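# Synthetic DEG tables and gene sets with exactly controlled overlap, so
# the enrichment statistics can be checked against construction.

#' DEG table simulation configuration
#'
#' Parameters for generating a differential-expression table together with
#' a sex-specific gene set and the detectable-gene universe, with the
#' overlap between illness DEGs and sex-specific genes fixed by
#' construction: `round(frac_sex_specific * n_genes)` genes are
#' sex-specific, exactly `n_illness_degs` genes pass the DEG filter, and
#' `round(frac_overlap * n_illness_degs)` of those are drawn from the
#' sex-specific set.
#'
#' @param n_genes Universe size.
#' @param frac_sex_specific Fraction of the universe that is sex-specific.
#' @param n_illness_degs Number of genes passing the DEG filter.
#' @param frac_overlap Fraction of illness DEGs that are sex-specific.
#' @param effect_size_log2 List with `min` (minimum absolute log2 fold
#'   change of a DEG, matching the filter cutoff) and `rate` (rate of the
#'   exponential tail above it).
#' @param seed Integer seed.
#' @return A `deg_sim_config` list.
#' @export
deg_sim_config <- function(n_genes = 19462L, frac_sex_specific = 2327 / 19462,
                           n_illness_degs = 41L, frac_overlap = 25 / 41,
                           effect_size_log2 = list(min = 1, rate = 1),
                           seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes", lower = 1L)
  frac_sex_specific <- check_number(frac_sex_specific, "frac_sex_specific",
                                    lower = 0, upper = 1)
  n_illness_degs <- check_count(n_illness_degs, "n_illness_degs", lower = 0L)
  frac_overlap <- check_number(frac_overlap, "frac_overlap",
                               lower = 0, upper = 1)
  if (n_illness_degs > n_genes) {
    stop_twindff("`n_illness_degs` cannot exceed `n_genes`.", "config")
  }
  n_sex <- round(frac_sex_specific * n_genes)
  n_overlap <- round(frac_overlap * n_illness_degs)
  if (n_overlap > n_sex) {
    stop_twindff("requested overlap exceeds the number of sex-specific genes.",
                 "config")
  }
  if (n_illness_degs - n_overlap > n_genes - n_sex) {
    stop_twindff("requested non-overlapping DEGs exceed the non-sex-specific pool.",
                 "config")
  }
  structure(list(n_genes = n_genes, frac_sex_specific = frac_sex_specific,
                 n_illness_degs = n_illness_degs, frac_overlap = frac_overlap,
                 effect_size_log2 = effect_size_log2,
                 seed = check_count(seed, "seed", lower = 0L)),
            class = "deg_sim_config")
}

#' Simulate a DEG table with controlled sex-specific overlap
#'
#' @param cfg A [deg_sim_config()].
#' @return List with `deg_table` (tibble `gene_id`, `log2fc`, `padj`),
#'   `sex_specific` (character vector) and `universe` (character vector).
#'   By construction [filter_degs()] on `deg_table` returns exactly
#'   `n_illness_degs` genes, of which `round(frac_overlap * n_illness_degs)`
#'   are in `sex_specific`.
#' @export
#' @examples
#' sim <- simulate_deg_tables(deg_sim_config(n_genes = 100,
#'   frac_sex_specific = 0.2, n_illness_degs = 10, frac_overlap = 0.5))
#' length(intersect(filter_degs(sim$deg_table), sim$sex_specific))  # 5
simulate_deg_tables <- function(cfg = deg_sim_config()) {
  stopifnot(inherits(cfg, "deg_sim_config"))
  with_seed(cfg$seed, {
    universe <- sprintf("gene_%05d", seq_len(cfg$n_genes))
    n_sex <- round(cfg$frac_sex_specific * cfg$n_genes)
    n_overlap <- round(cfg$frac_overlap * cfg$n_illness_degs)
    sex_specific <- sort(sample(universe, n_sex))
    non_sex <- setdiff(universe, sex_specific)
    degs <- sort(c(
      if (n_overlap > 0) sample(sex_specific, n_overlap) else character(),
      if (cfg$n_illness_degs - n_overlap > 0) {
        sample(non_sex, cfg$n_illness_degs - n_overlap)
      } else character()))

    is_deg <- universe %in% degs
    n_deg <- sum(is_deg)
    lfc <- rnorm(cfg$n_genes, 0, 0.4)
    padj <- runif(cfg$n_genes, 0.05, 1)
    es <- cfg$effect_size_log2
    lfc[is_deg] <- sample(c(-1, 1), n_deg, replace = TRUE) *
      (es$min + rexp(n_deg, es$rate))
    padj[is_deg] <- runif(n_deg, 1e-10, 0.05 * (1 - 1e-9))
    list(deg_table = tibble::tibble(gene_id = universe, log2fc = lfc,
                                    padj = padj),
         sex_specific = sex_specific,
         universe = universe)
  })
}
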