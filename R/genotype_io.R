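#' Read Plink-style text PED/MAP files into a trio study
#'
#' PED rows carry six pedigree columns (family, individual, father, mother,
#' sex, affection) followed by two allele columns per MAP SNP; fields are
#' whitespace-separated and a missing allele is coded `"0"`. MAP rows carry
#' chromosome, SNP ID, genetic distance and 1-based physical position.
#' A genotype with either allele missing is treated as missing.
#'
#' @param ped_path Path to the PED file.
#' @param map_path Path to the MAP file.
#' @return A [trio_study()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "\\s+")
  bad <- which(lengths(map_tok) != 4L)
  if (length(bad) > 0) {
    ptr_abort(sprintf("MAP line %d: expected 4 columns, found %d",
                      bad[1], lengths(map_tok)[bad[1]]), "pathtrio_format_error")
  }
  map <- do.call(rbind, map_tok)
  snp_id <- map[, 2]
  ptr_assert(!anyDuplicated(snp_id), "duplicate snp_id in MAP file",
             "pathtrio_format_error")
  n_snp <- length(snp_id)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_tok <- strsplit(trimws(ped_lines), "\\s+")
  want <- 6L + 2L * n_snp
  bad <- which(lengths(ped_tok) != want)
  if (length(bad) > 0) {
    ptr_abort(sprintf(
      "PED line %d: expected %d fields (6 pedigree + 2 alleles x %d MAP SNPs), found %d",
      bad[1], want, n_snp, lengths(ped_tok)[bad[1]]), "pathtrio_format_error")
  }
  ped <- do.call(rbind, ped_tok)
  n_ind <- nrow(ped)

  individuals <- tibble::tibble(
    family_id = ped[, 1], individual_id = ped[, 2],
    father_id = ped[, 3], mother_id = ped[, 4],
    sex = as.integer(ped[, 5]), affection = as.integer(ped[, 6])
  )

  a1 <- ped[, 6L + 2L * seq_len(n_snp) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(n_snp), drop = FALSE]
  miss <- a1 == "0" | a2 == "0"
  a1[miss] <- NA_character_
  a2[miss] <- NA_character_

  allele_a <- character(n_snp)
  allele_b <- character(n_snp)
  geno <- matrix(NA_integer_, n_ind, n_snp)
  for (j in seq_len(n_snp)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- unique(obs[!is.na(obs)])
    if (length(alleles) > 2) {
      ptr_abort(sprintf("SNP %s: more than two alleles observed (%s)",
                        snp_id[j], paste(alleles, collapse = ", ")),
                "pathtrio_format_error")
    }
    allele_a[j] <- if (length(alleles) >= 1) alleles[1] else NA_character_
    allele_b[j] <- if (length(alleles) == 2) alleles[2] else NA_character_
    if (is.na(allele_b[j])) {
      geno[, j] <- ifelse(miss[, j], NA_integer_, 0L)
    } else {
      geno[, j] <- (a1[, j] == allele_b[j]) + (a2[, j] == allele_b[j])
    }
  }

  snps <- tibble::tibble(
    snp_id = snp_id, chrom = map[, 1], pos = as.integer(map[, 4]),
    allele_a = allele_a, allele_b = allele_b
  )
  trio_study(individuals, snps, geno)
}

#' Write a trio study as Plink-style text PED/MAP
#'
#' Heterozygous genotypes are written in canonical `allele_a allele_b` order;
#' missing genotypes as `0 0`.
#'
#' @param x A [trio_study()].
#' @param ped_path,map_path Output paths.
#' @return Invisibly, `x`.
#' @export
write_ped_map <- function(x, ped_path, map_path) {
  s <- x$snps
  writeLines(paste(s$chrom, s$snp_id, 0, s$pos, sep = "\t"), map_path)

  n_snp <- nrow(s)
  aa <- ifelse(is.na(s$allele_a), "0", s$allele_a)
  ab <- ifelse(is.na(s$allele_b), "0", s$allele_b)
  g <- x$geno
  a1 <- matrix(rep(aa, each = nrow(g)), nrow(g), n_snp)
  a2 <- a1
  bmat <- matrix(rep(ab, each = nrow(g)), nrow(g), n_snp)
  i1 <- which(g >= 1)
  a2[i1] <- bmat[i1]       # heterozygotes in canonical "a b" order
  i2 <- which(g == 2)
  a1[i2] <- bmat[i2]
  im <- which(is.na(g))
  a1[im] <- "0"
  a2[im] <- "0"
  gt <- matrix(paste(a1, a2), nrow(g), n_snp)

  ind <- x$individuals
  lines <- paste(ind$family_id, ind$individual_id, ind$father_id, ind$mother_id,
                 ind$sex, ind$affection)
  if (n_snp > 0) {
    lines <- paste(lines, apply(gt, 1, paste, collapse = " "))
  }
  writeLines(lines, ped_path)
  invisible(x)
}

#' Read a SNP annotation table
#'
#' Tab-separated with header columns `snp_id`, `gene`, `func_class`; the
#' functional class must be one of `missense`, `splice`, `none`
#' (case-insensitive). These three classes are the matching strata used by
#' the permutation null.
#'
#' @param tsv_path Path to the TSV file.
#' @return Tibble with columns `snp_id`, `gene`, `func_class`.
#' @export
read_annotation <- function(tsv_path) {
  ann <- readr::read_tsv(tsv_path, col_types = readr::cols(.default = readr::col_character()))
  need <- c("snp_id", "gene", "func_class")
  ptr_assert(all(need %in% names(ann)),
             paste("annotation must have columns:", paste(need, collapse = ", ")),
             "pathtrio_format_error")
  ann$func_class <- tolower(ann$func_class)
  valid <- c("missense", "splice", "none")
  bad <- setdiff(unique(ann$func_class), valid)
  if (length(bad) > 0) {
    ptr_abort(sprintf("unknown func_class '%s'; accepted tokens: %s",
                      bad[1], paste(valid, collapse = ", ")),
              "pathtrio_format_error")
  }
  if (anyDuplicated(ann$snp_id)) {
    dup <- ann$snp_id[duplicated(ann$snp_id)][1]
    ptr_abort(sprintf("duplicate snp_id in annotation: %s", dup),
              "pathtrio_format_error")
  }
  ann[need]
}

#' Write a SNP annotation table
#' @param annotation Tibble with `snp_id`, `gene`, `func_class`.
#' @param tsv_path Output path.
#' @export
write_annotation <- function(annotation, tsv_path) {
  readr::write_tsv(annotation, tsv_path)
  invisible(annotation)
}

#' Read gene sets in GMT format
#'
#' One set per line: `set_id TAB description TAB gene1 TAB gene2 ...`.
#' Genes are de-duplicated within a set; duplicate set IDs are an error.
#'
#' @param gmt_path Path to the GMT file.
#' @return A `gene_set_db`: tibble with columns `set_id`, `description`,
#'   `genes` (list column), `n_genes`.
#' @export
read_gmt <- function(gmt_path) {
  lines <- readLines(gmt_path)
  lines <- lines[nzchar(lines)]
  tok <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(tok) < 3L)
  if (length(bad) > 0) {
    ptr_abort(sprintf("GMT line %d: expected at least 3 tab-separated fields", bad[1]),
              "pathtrio_format_error")
  }
  db <- tibble::tibble(
    set_id = vapply(tok, `[[`, "", 1L),
    description = vapply(tok, `[[`, "", 2L),
    genes = lapply(tok, function(x) unique(x[-(1:2)]))
  )
  if (anyDuplicated(db$set_id)) {
    ptr_abort(sprintf("duplicate set_id in GMT: %s",
                      db$set_id[duplicated(db$set_id)][1]),
              "pathtrio_format_error")
  }
  db$n_genes <- lengths(db$genes)
  class(db) <- c("gene_set_db", class(db))
  db
}

#' Write gene sets in GMT format
#' @param db A `gene_set_db` (see [read_gmt()]).
#' @param gmt_path Output path.
#' @export
write_gmt <- function(db, gmt_path) {
  lines <- vapply(seq_len(nrow(db)), function(i) {
    paste(c(db$set_id[i], db$description[i], db$genes[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, gmt_path)
  invisible(db)
}

#' Build a gene_set_db from a named list
#' @param sets Named list of character gene vectors.
#' @param descriptions Optional character vector parallel to `sets`.
#' @return A `gene_set_db`.
#' @export
gene_set_db <- function(sets, descriptions = NULL) {
  ptr_assert(!is.null(names(sets)) && !anyDuplicated(names(sets)),
             "sets must be a uniquely named list")
  db <- tibble::tibble(
    set_id = names(sets),
    description = descriptions %||% names(sets),
    genes = lapply(sets, unique)
  )
  db$n_genes <- lengths(db$genes)
  class(db) <- c("gene_set_db", class(db))
  db
}
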