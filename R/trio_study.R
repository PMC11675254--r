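#' Construct a trio study
#'
#' A `trio_study` bundles a pedigree, per-SNP metadata and a genotype matrix
#' for a family-based (trio) association study. Genotypes are stored as counts
#' of each SNP's `allele_b` (0, 1, 2, or `NA` for missing); allele polarity is
#' arbitrary at this stage — the minor allele is determined from founder
#' frequencies at analysis time, not from file or constructor order.
#'
#' Affected-offspring trios are derived automatically: every individual coded
#' affected whose `father_id` and `mother_id` both match individuals in the
#' same family contributes one trio. Individuals that do not complete a trio
#' (founders, offspring with a missing parent) are retained in the study.
#'
#' @param individuals Tibble with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`, `affection`. Affection is coded
#'   0 = missing, 1 = unaffected, 2 = affected; `"0"` marks an absent parent.
#' @param snps Tibble with columns `snp_id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b` and optionally `gene`, `func_class`. `allele_b` may be `NA`
#'   for monomorphic SNPs.
#' @param geno Integer matrix, individuals x SNPs, counting copies of
#'   `allele_b` (`NA` = missing genotype).
#'
#' @return An object of class `trio_study`.
#' @export
trio_study <- function(individuals, snps, geno) {
  individuals <- tibble::as_tibble(individuals)
  snps <- tibble::as_tibble(snps)
  need <- c("family_id", "individual_id", "father_id", "mother_id", "sex", "affection")
  ptr_assert(all(need %in% names(individuals)),
             paste("individuals must have columns:", paste(need, collapse = ", ")))
  need_snp <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  ptr_assert(all(need_snp %in% names(snps)),
             paste("snps must have columns:", paste(need_snp, collapse = ", ")))
  if (!"gene" %in% names(snps)) snps$gene <- NA_character_
  if (!"func_class" %in% names(snps)) snps$func_class <- "none"
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  ptr_assert(nrow(geno) == nrow(individuals) && ncol(geno) == nrow(snps),
             "genotype matrix dimensions must be (n_individuals, n_snps)")
  ptr_assert(!anyDuplicated(snps$snp_id), "duplicate snp_id in SNP table")
  keys <- ind_key(individuals$family_id, individuals$individual_id)
  dup <- keys[duplicated(keys)]
  if (length(dup) > 0) {
    ptr_abort(paste0("duplicate individual ID within a family: ", dup[1]),
              "pathtrio_format_error")
  }
  dimnames(geno) <- list(keys, snps$snp_id)
  out <- structure(
    list(individuals = individuals, snps = snps, geno = geno),
    class = "trio_study"
  )
  out$trios <- derive_trios(individuals)
  out
}

# trios: affected offspring with both parents present in the same family.
# Sorted by (family_id, offspring_id) so the result is independent of the
# input row order.
derive_trios <- function(individuals) {
  keys <- ind_key(individuals$family_id, individuals$individual_id)
  row_of <- setNames(seq_along(keys), keys)
  is_off <- individuals$affection == 2 &
    individuals$father_id != "0" & individuals$mother_id != "0"
  fk <- ind_key(individuals$family_id, individuals$father_id)
  mk <- ind_key(individuals$family_id, individuals$mother_id)
  ok <- is_off & fk %in% keys & mk %in% keys
  out <- tibble::tibble(
    family_id = individuals$family_id[ok],
    offspring_id = individuals$individual_id[ok],
    father = unname(row_of[fk[ok]]),
    mother = unname(row_of[mk[ok]]),
    offspring = which(ok)
  )
  dplyr::arrange(out, .data$family_id, .data$offspring_id)
}

#' @export
print.trio_study <- function(x, ...) {
  cat("<trio_study> ", nrow(x$individuals), " individuals, ",
      nrow(x$snps), " SNPs, ", nrow(x$trios), " affected-offspring trios\n",
      sep = "")
  invisible(x)
}

#' Number of trios, individuals and SNPs in a study
#' @param x A `trio_study`.
#' @return Named integer vector.
#' @export
study_dim <- function(x) {
  c(individuals = nrow(x$individuals), snps = nrow(x$snps), trios = nrow(x$trios))
}

#' Is each individual a founder?
#'
#' Founders have no parents in the dataset (both parent IDs `"0"`).
#' @param x A `trio_study`.
#' @return Logical vector along the individual table.
#' @export
is_founder <- function(x) {
  x$individuals$father_id == "0" & x$individuals$mother_id == "0"
}

#' Subset a study to a set of SNPs
#' @param x A `trio_study`.
#' @param snp_ids Character vector of SNP IDs to keep, in study order.
#' @return A `trio_study` restricted to those SNPs.
#' @export
subset_snps <- function(x, snp_ids) {
  keep <- x$snps$snp_id %in% snp_ids
  ptr_assert(any(keep), "no SNPs left after subset", "pathtrio_empty_study")
  trio_study(x$individuals, x$snps[keep, , drop = FALSE], x$geno[, keep, drop = FALSE])
}

#' Attach SNP annotation to a study
#'
#' Joins a SNP -> (gene, functional class) map onto the study's SNP table.
#' SNPs absent from the annotation get `gene = NA` and `func_class = "none"`.
#'
#' @param x A `trio_study`.
#' @param annotation Tibble as returned by [read_annotation()].
#' @return The study with `gene` and `func_class` filled in.
#' @export
annotate_study <- function(x, annotation) {
  ann <- tibble::as_tibble(annotation)
  m <- match(x$snps$snp_id, ann$snp_id)
  x$snps$gene <- ifelse(is.na(m), NA_character_, ann$gene[m])
  x$snps$func_class <- ifelse(is.na(m), "none", ann$func_class[m])
  x
}
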