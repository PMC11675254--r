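#' Run the full two-phase pathway analysis
#'
#' Phase 1 (investigation sample): QC, per-SNP TDT, inflation screen
#' (lambda, QQ coordinates), genelist1, gene-set over-representation, index
#' pathway selection, and the matched-permutation enrichment verdict.
#' Phase 2 (replication sample): QC, TDT, selection of index-pathway SNPs
#' that are available and direction-concordant, the within-pathway
#' prevalence statistic at the 0.05 and 0.01 levels, the replication
#' permutation verdict, and the final replicated / not-replicated decision.
#'
#' When no gene set passes the enrichment threshold the run stops cleanly
#' with outcome `"no_index_pathway"`; when no SNP survives the replication
#' selection the outcome is `"no_replication_snps"`.
#'
#' @param investigation,replication `sim_study` lists from
#'   [simulate_study()]/[simulate_pair()], or annotated [trio_study()]
#'   objects.
#' @param gene_sets A `gene_set_db`; defaults to the investigation
#'   `sim_study`'s own sets when available.
#' @param qc A [qc_config()], or `NULL` to skip QC.
#' @param p_genelist1 Association threshold feeding genelist1 (default 0.001).
#' @param enrich_alpha Adjusted-p threshold for the index pathway (default 0.05).
#' @param perm A [perm_config()].
#' @param levels Nominal significance levels for prevalence and permutation
#'   counts.
#' @param strict_p_threshold Passed to [select_replication_snps()].
#' @return A `pathway_run` list; see [glance.pathway_run()] for the one-row
#'   summary and [write_run_report()] to dump all tables.
#' @export
run_pipeline <- function(investigation, replication, gene_sets = NULL,
                         qc = qc_config(), p_genelist1 = 0.001,
                         enrich_alpha = 0.05, perm = perm_config(),
                         levels = c(0.05, 0.01), strict_p_threshold = NULL) {
  if (inherits(investigation, "sim_study")) {
    gene_sets <- gene_sets %||% investigation$gene_sets
    investigation <- investigation$study
  }
  if (inherits(replication, "sim_study")) replication <- replication$study
  ptr_assert(!is.null(gene_sets), "gene_sets is required", "pathtrio_missing_config")

  out <- list(levels = levels, perm = perm,
              outcome = "ok", decision = "not_replicated")

  # ---- Phase 1: investigation ----
  if (!is.null(qc)) {
    qc_inv <- apply_qc(investigation, qc)
    out$qc_inv <- qc_inv$report
    investigation <- qc_inv$study
  }
  inv_results <- tdt_scan(investigation)
  out$inv_results <- inv_results
  out$lambda_inv <- genomic_lambda(inv_results)
  out$qq_inv <- qq_coordinates(inv_results)
  out$genelist1 <- build_genelist1(inv_results, p_genelist1)
  universe <- sort(unique(inv_results$gene[!is.na(inv_results$gene)]))
  if (length(out$genelist1) == 0) {
    out$outcome <- "no_index_pathway"
    return(structure(out, class = "pathway_run"))
  }
  out$enrichment <- enrich_gene_sets(out$genelist1, gene_sets, universe)
  index <- select_index_pathway(out$enrichment, gene_sets, investigation,
                                alpha = enrich_alpha)
  if (is.null(index)) {
    out$outcome <- "no_index_pathway"
    return(structure(out, class = "pathway_run"))
  }
  out$index_pathway <- index
  out$verdict_inv <- permutation_test(inv_results, index$snp_ids, perm, levels)

  # ---- Phase 2: replication ----
  if (!is.null(qc)) {
    qc_rep <- apply_qc(replication, qc)
    out$qc_rep <- qc_rep$report
    replication <- qc_rep$study
  }
  rep_results <- tdt_scan(replication)
  out$rep_results <- rep_results
  out$lambda_rep <- genomic_lambda(rep_results)
  out$qq_rep <- qq_coordinates(rep_results)
  out$selection <- select_replication_snps(index, inv_results, rep_results,
                                           strict_p_threshold)
  if (nrow(out$selection) == 0) {
    out$outcome <- "no_replication_snps"
    return(structure(out, class = "pathway_run"))
  }
  out$prevalence <- prevalence(out$selection, levels)
  out$verdict_rep <- permutation_test(rep_results, out$selection$snp_id,
                                      perm, levels)
  out$decision <- decide_replication(out$verdict_inv, out$verdict_rep)
  structure(out, class = "pathway_run")
}

#' @export
print.pathway_run <- function(x, ...) {
  cat("<pathway_run> outcome:", x$outcome, "\n")
  if (!is.null(x$lambda_inv))
    cat(sprintf("  lambda (investigation): %.3f\n", x$lambda_inv))
  if (!is.null(x$genelist1))
    cat("  genelist1:", length(x$genelist1), "genes\n")
  if (!is.null(x$index_pathway))
    cat("  index pathway:", x$index_pathway$set_id, "with",
        length(x$index_pathway$snp_ids), "SNPs\n")
  if (!is.null(x$lambda_rep))
    cat(sprintf("  lambda (replication): %.3f\n", x$lambda_rep))
  if (!is.null(x$selection))
    cat("  replication selection:", nrow(x$selection), "SNPs\n")
  if (!is.null(x$prevalence)) {
    for (i in seq_len(nrow(x$prevalence))) {
      cat(sprintf("  prevalence at %.2f: %.3f (%+.0f%% vs expected)\n",
                  x$prevalence$level[i], x$prevalence$prevalence[i],
                  x$prevalence$relative_excess_pct[i]))
    }
  }
  if (!is.null(x$verdict_inv))
    cat("  investigation verdict:", x$verdict_inv$decision,
        sprintf("(exceedance %.4f / %.4f)\n",
                x$verdict_inv$exceed_frac_05, x$verdict_inv$exceed_frac_01))
  if (!is.null(x$verdict_rep))
    cat("  replication verdict:", x$verdict_rep$decision,
        sprintf("(exceedance %.4f / %.4f)\n",
                x$verdict_rep$exceed_frac_05, x$verdict_rep$exceed_frac_01))
  cat("  decision:", x$decision, "\n")
  invisible(x)
}

#' One-row summary of a pipeline run
#'
#' @param x A `pathway_run` from [run_pipeline()].
#' @param ... Ignored.
#' @return A one-row tibble with every number needed to audit the decision.
#' @exportS3Method generics::glance
glance.pathway_run <- function(x, ...) {
  sel_n <- if (!is.null(x$selection)) nrow(x$selection) else NA_integer_
  prev <- function(lv, col) {
    if (is.null(x$prevalence)) return(NA_real_)
    v <- x$prevalence[[col]][x$prevalence$level == lv]
    if (length(v)) v else NA_real_
  }
  tibble::tibble(
    outcome = x$outcome,
    lambda_inv = x$lambda_inv %||% NA_real_,
    lambda_rep = x$lambda_rep %||% NA_real_,
    n_genelist1 = if (!is.null(x$genelist1)) length(x$genelist1) else NA_integer_,
    index_set = if (!is.null(x$index_pathway)) x$index_pathway$set_id else NA_character_,
    n_pathway_snps = if (!is.null(x$index_pathway)) length(x$index_pathway$snp_ids) else NA_integer_,
    n_selected = sel_n,
    prevalence_05 = prev(x$levels[1], "prevalence"),
    prevalence_01 = prev(x$levels[2], "prevalence"),
    excess_pct_05 = prev(x$levels[1], "relative_excess_pct"),
    excess_pct_01 = prev(x$levels[2], "relative_excess_pct"),
    exceed_inv_05 = if (!is.null(x$verdict_inv)) x$verdict_inv$exceed_frac_05 else NA_real_,
    exceed_inv_01 = if (!is.null(x$verdict_inv)) x$verdict_inv$exceed_frac_01 else NA_real_,
    exceed_rep_05 = if (!is.null(x$verdict_rep)) x$verdict_rep$exceed_frac_05 else NA_real_,
    exceed_rep_01 = if (!is.null(x$verdict_rep)) x$verdict_rep$exceed_frac_01 else NA_real_,
    decision = x$decision
  )
}

#' Tidy per-level summary of a pipeline run
#' @param x A `pathway_run`.
#' @param ... Ignored.
#' @return Tibble with prevalence and permutation rows per nominal level.
#' @exportS3Method generics::tidy
tidy.pathway_run <- function(x, ...) {
  parts <- list()
  if (!is.null(x$prevalence)) parts$prevalence <- x$prevalence
  if (!is.null(x$verdict_inv)) {
    parts$inv <- dplyr::mutate(tidy(x$verdict_inv), sample = "investigation")
  }
  if (!is.null(x$verdict_rep)) {
    parts$rep <- dplyr::mutate(tidy(x$verdict_rep), sample = "replication")
  }
  perm_tbl <- dplyr::bind_rows(parts[c("inv", "rep")])
  if (!is.null(parts$prevalence) && nrow(perm_tbl) > 0) {
    dplyr::full_join(parts$prevalence, perm_tbl, by = "level")
  } else if (nrow(perm_tbl) > 0) {
    perm_tbl
  } else {
    parts$prevalence %||% tibble::tibble()
  }
}

#' Write every table of a pipeline run to a directory
#'
#' Emits the QC reports, TDT result tables, QQ coordinates, enrichment
#' table, index-pathway gene and SNP lists, replication selection,
#' prevalence summary, permutation summary and a human-readable
#' `summary.txt` (including lambda values, seeds and permutation counts).
#'
#' @param run A `pathway_run`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  put <- function(obj, name) {
    p <- file.path(dir, name)
    readr::write_tsv(obj, p)
    paths <<- c(paths, p)
  }
  if (!is.null(run$qc_inv)) put(run$qc_inv, "qc_investigation.tsv")
  if (!is.null(run$qc_rep)) put(run$qc_rep, "qc_replication.tsv")
  if (!is.null(run$inv_results)) put(run$inv_results, "tdt_investigation.tsv")
  if (!is.null(run$rep_results)) put(run$rep_results, "tdt_replication.tsv")
  if (!is.null(run$qq_inv)) put(run$qq_inv, "qq_investigation.tsv")
  if (!is.null(run$qq_rep)) put(run$qq_rep, "qq_replication.tsv")
  if (!is.null(run$enrichment)) put(run$enrichment, "enrichment.tsv")
  if (!is.null(run$index_pathway)) {
    writeLines(run$index_pathway$genes, file.path(dir, "genelist2.txt"))
    ip <- run$index_pathway
    put(tibble::tibble(snp_id = ip$snp_ids), "index_pathway_snps.tsv")
  }
  if (!is.null(run$selection)) {
    sel <- run$selection
    sel$significant_at_005 <- sel$p_rep < 0.05
    sel$significant_at_001 <- sel$p_rep < 0.01
    put(sel, "replication_selection.tsv")
  }
  if (!is.null(run$prevalence)) put(run$prevalence, "prevalence.tsv")
  verd <- list()
  if (!is.null(run$verdict_inv)) {
    verd$inv <- dplyr::mutate(tidy(run$verdict_inv), sample = "investigation")
  }
  if (!is.null(run$verdict_rep)) {
    verd$rep <- dplyr::mutate(tidy(run$verdict_rep), sample = "replication")
  }
  if (length(verd) > 0) put(dplyr::bind_rows(verd), "permutation_summary.tsv")

  con <- file.path(dir, "summary.txt")
  lines <- c(
    paste("outcome:", run$outcome),
    paste("decision:", run$decision),
    if (!is.null(run$lambda_inv)) sprintf("lambda_investigation: %.4f", run$lambda_inv),
    if (!is.null(run$lambda_rep)) sprintf("lambda_replication: %.4f", run$lambda_rep),
    if (!is.null(run$genelist1)) paste("genelist1_size:", length(run$genelist1)),
    if (!is.null(run$index_pathway)) c(
      paste("index_pathway:", run$index_pathway$set_id),
      paste("index_pathway_snps:", length(run$index_pathway$snp_ids))
    ),
    if (!is.null(run$selection)) paste("replication_selected_snps:", nrow(run$selection)),
    paste("n_perm:", run$perm$n_perm),
    paste("perm_seed:", run$perm$seed %||% "none"),
    paste("thresholds:", run$perm$alpha_05, run$perm$alpha_01)
  )
  writeLines(lines, con)
  paths <- c(paths, con)
  invisible(paths)
}
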