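#' Genes harbouring associated SNPs (genelist1)
#'
#' Selects the unique genes that harbour at least one SNP with a TDT
#' p-value below the threshold. SNPs with no mapped gene are dropped.
#' The default threshold of 0.001 prioritises the strongest associations
#' while retaining enough genes to feed the over-representation step.
#'
#' @param results Annotated tibble from [tdt_scan()] (needs `gene`, `p`).
#' @param p_threshold Association p-value cutoff, in `(0, 1)`.
#' @return Character vector of gene symbols (alphabetical). Empty with a
#'   warning when nothing passes.
#' @export
build_genelist1 <- function(results, p_threshold = 0.001) {
  ptr_assert(p_threshold > 0 && p_threshold < 1, "p_threshold must be in (0, 1)")
  genes <- sort(unique(results$gene[!is.na(results$gene) & results$p < p_threshold]))
  if (length(genes) == 0) {
    warn("no genes pass the association threshold; genelist1 is empty")
  }
  genes
}

#' Gene-set over-representation by the hypergeometric test
#'
#' For each set, tests whether the query genes overlap the set more than
#' expected when drawing `length(query)` genes from the universe: the
#' upper-tail hypergeometric probability `P(X >= overlap)`. P-values are
#' adjusted across sets by Benjamini-Hochberg.
#'
#' The universe should be the genes actually represented on the post-QC SNP
#' panel (not the whole genome), which avoids array-coverage bias.
#'
#' @param query Character vector of genes (e.g. from [build_genelist1()]);
#'   must be a subset of `universe`.
#' @param db A `gene_set_db` (see [read_gmt()]).
#' @param universe Character vector of background genes.
#' @return Tibble with one row per set, sorted by `p_hyper`: `set_id`,
#'   `description`, `set_size_in_universe`, `overlap`, `query_size`,
#'   `universe_size`, `p_hyper`, `p_adj`.
#' @export
enrich_gene_sets <- function(query, db, universe) {
  query <- unique(query)
  universe <- unique(universe)
  ptr_assert(length(query) > 0, "empty query gene list", "pathtrio_empty_query")
  ptr_assert(length(universe) > 0, "empty universe", "pathtrio_empty_query")
  ptr_assert(all(query %in% universe), "query must be a subset of the universe")
  set_in_uni <- unname(vapply(db$genes, function(g) sum(g %in% universe), integer(1)))
  overlap <- unname(vapply(db$genes, function(g) sum(g %in% query), integer(1)))
  n_uni <- length(universe)
  n_query <- length(query)
  p <- phyper(overlap - 1, set_in_uni, n_uni - set_in_uni, n_query,
              lower.tail = FALSE)
  out <- tibble::tibble(
    set_id = db$set_id,
    description = db$description,
    set_size_in_universe = set_in_uni,
    overlap = overlap,
    query_size = n_query,
    universe_size = n_uni,
    p_hyper = p,
    p_adj = p.adjust(p, method = "BH")
  )
  dplyr::arrange(out, .data$p_hyper, dplyr::desc(.data$overlap), .data$set_id)
}

#' Select the index pathway from enrichment results
#'
#' The index pathway is the single gene set with the smallest adjusted
#' p-value below `alpha` (ties broken by larger overlap, then lexicographic
#' `set_id`). Its full gene list becomes genelist2, and its SNP universe is
#' every study SNP mapped to one of those genes — not only the sub-threshold
#' ones — with counts per functional class.
#'
#' @param rows Tibble from [enrich_gene_sets()].
#' @param db The `gene_set_db` the rows were computed from.
#' @param study The (annotated, post-QC) [trio_study()] supplying the SNP map.
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return An `index_pathway` (list with `set_id`, `p_adj`, `genes`,
#'   `snp_ids`, `class_counts`), or `NULL` when no set passes — the clean
#'   "no index pathway" outcome.
#' @export
select_index_pathway <- function(rows, db, study, alpha = 0.05) {
  ptr_assert(nrow(rows) > 0, "no enrichment rows")
  hits <- dplyr::filter(rows, .data$p_adj < alpha)
  if (nrow(hits) == 0) {
    message("no gene set passes alpha = ", alpha, ": no index pathway")
    return(NULL)
  }
  best <- dplyr::arrange(hits, .data$p_adj, dplyr::desc(.data$overlap), .data$set_id)[1, ]
  genes <- db$genes[[match(best$set_id, db$set_id)]]
  in_path <- !is.na(study$snps$gene) & study$snps$gene %in% genes
  snp_ids <- study$snps$snp_id[in_path]
  cls <- factor(study$snps$func_class[in_path],
                levels = c("missense", "splice", "none"))
  structure(
    list(set_id = best$set_id, p_adj = best$p_adj, genes = genes,
         snp_ids = snp_ids,
         class_counts = setNames(as.integer(table(cls)), levels(cls))),
    class = "index_pathway"
  )
}

#' @export
print.index_pathway <- function(x, ...) {
  cat("<index_pathway> ", x$set_id, " (p_adj = ", signif(x$p_adj, 3), "): ",
      length(x$genes), " genes, ", length(x$snp_ids), " SNPs [",
      paste(names(x$class_counts), x$class_counts, sep = ":", collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Bar chart of gene-set enrichment
#' @param rows Tibble from [enrich_gene_sets()].
#' @param top Number of sets to show.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(rows, top = 10) {
  d <- head(dplyr::arrange(rows, .data$p_adj), top)
  d$set_id <- factor(d$set_id, levels = rev(d$set_id))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p_adj), y = .data$set_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10](adjusted ~ p)), y = NULL) +
    ggplot2::theme_minimal()
}
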