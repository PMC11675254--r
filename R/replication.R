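#' Select index-pathway SNPs for the replication analysis
#'
#' Keeps the SNPs that (i) belong to the index pathway, (ii) are present in
#' the replication results, and (iii) show the same direction of association
#' (odds ratio on the same side of 1) in both samples. An infinite OR
#' (all transmissions, no non-transmissions) counts as risk-directional; an
#' OR of exactly 1, or an undefined OR (no informative transmissions), is
#' non-directional and excluded. Optionally an investigation-sample p-value
#' filter can be added via `strict_p_threshold`.
#'
#' @param index An `index_pathway` from [select_index_pathway()].
#' @param inv_results,rep_results Tibbles from [tdt_scan()] on the
#'   investigation and replication samples.
#' @param strict_p_threshold Optional: additionally require the
#'   investigation p-value below this threshold (e.g. 0.001). `NULL` (the
#'   default) filters on membership, availability and direction only.
#' @return Tibble of class `replication_selection`: `snp_id`, `gene`,
#'   `func_class`, `or_inv`, `or_rep`, `p_inv`, `p_rep`. Attributes
#'   `n_selected` and `class_counts`. Empty selection triggers a warning.
#' @export
select_replication_snps <- function(index, inv_results, rep_results,
                                    strict_p_threshold = NULL) {
  inv <- dplyr::filter(inv_results, .data$snp_id %in% index$snp_ids)
  joined <- dplyr::inner_join(
    dplyr::select(inv, "snp_id", "gene", "func_class",
                  or_inv = "or", p_inv = "p"),
    dplyr::select(rep_results, "snp_id", or_rep = "or", p_rep = "p"),
    by = "snp_id"
  )
  dir_of <- function(or) {
    # sign of (or - 1); Inf -> +1; NA or exactly 1 -> 0 (non-directional)
    ifelse(is.na(or), 0, sign(or - 1))
  }
  di <- dir_of(joined$or_inv)
  dr <- dir_of(joined$or_rep)
  keep <- di != 0 & dr != 0 & di == dr
  if (!is.null(strict_p_threshold)) {
    keep <- keep & joined$p_inv < strict_p_threshold
  }
  out <- joined[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    warn("no index-pathway SNPs pass the replication selection filters")
  }
  cls <- factor(out$func_class, levels = c("missense", "splice", "none"))
  attr(out, "n_selected") <- nrow(out)
  attr(out, "class_counts") <- setNames(as.integer(table(cls)), levels(cls))
  class(out) <- c("replication_selection", class(out))
  out
}

#' Within-pathway prevalence of significant replication associations
#'
#' The prevalence statistic is the fraction of selected index-pathway SNPs
#' whose replication p-value falls below a nominal level; under no
#' enrichment its expectation is the level itself, so the relative excess
#' `100 * (prevalence - level) / level` measures how far the pathway exceeds
#' chance (e.g. a prevalence of 6.4% at level 0.05 is a 28% relative excess).
#'
#' @param selection A `replication_selection` from
#'   [select_replication_snps()] (carries `p_rep`).
#' @param level Nominal significance level, in `(0, 1)`; typically 0.05 or
#'   0.01. Vectorised.
#' @return Tibble, one row per level: `level`, `n_selected`,
#'   `n_significant`, `prevalence`, `expected`, `relative_excess_pct`.
#' @export
prevalence <- function(selection, level = c(0.05, 0.01)) {
  n_sel <- nrow(selection)
  ptr_assert(n_sel > 0, "empty replication selection: prevalence undefined",
             "pathtrio_empty_selection")
  dplyr::bind_rows(lapply(level, function(l) {
    prevalence_from_counts(sum(selection$p_rep < l), n_sel, l)
  }))
}

#' Prevalence and relative excess from raw counts
#'
#' @param n_significant Number of selected SNPs significant at `level`.
#' @param n_selected Total number of selected SNPs (> 0).
#' @param level Nominal significance level in `(0, 1)`.
#' @return One-row tibble as in [prevalence()].
#' @export
prevalence_from_counts <- function(n_significant, n_selected, level) {
  ptr_assert(level > 0 && level < 1, "level must be in (0, 1)")
  ptr_assert(n_selected > 0, "n_selected must be > 0", "pathtrio_empty_selection")
  ptr_assert(n_significant >= 0 && n_significant <= n_selected,
             "n_significant must be in [0, n_selected]")
  prev <- n_significant / n_selected
  tibble::tibble(
    level = level,
    n_selected = as.integer(n_selected),
    n_significant = as.integer(n_significant),
    prevalence = prev,
    expected = level,
    relative_excess_pct = 100 * (prev - level) / level
  )
}
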