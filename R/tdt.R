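#' TDT statistics from transmitted/untransmitted counts
#'
#' The Transmission Disequilibrium Test compares the number of times
#' heterozygous parents transmit the minor allele to an affected offspring
#' (`t`) against the number of times they do not (`u`). The statistic is
#' `(t - u)^2 / (t + u)` on 1 df, with the two-sided p-value from the
#' chi-square approximation. The odds ratio is `t / u`: infinite when
#' `u = 0, t > 0`, undefined (`NA`) when both are zero.
#'
#' @param t,u Non-negative transmission counts (vectorised).
#' @param snp_id Optional SNP IDs carried through to the output.
#' @return Tibble with `t`, `u`, `or`, `chi2`, `p`, `n_informative`.
#' @export
tdt_from_counts <- function(t, u, snp_id = NULL) {
  ptr_assert(all(t >= 0) && all(u >= 0), "counts must be non-negative")
  n_inf <- t + u
  chi2 <- ifelse(n_inf > 0, (t - u)^2 / n_inf, 0)
  p <- ifelse(n_inf > 0, pchisq(chi2, df = 1, lower.tail = FALSE), 1)
  or <- ifelse(u > 0, t / u, ifelse(t > 0, Inf, NA_real_))
  out <- tibble::tibble(t = as.integer(t), u = as.integer(u), or = or,
                        chi2 = chi2, p = p, n_informative = as.integer(n_inf))
  if (!is.null(snp_id)) out <- dplyr::bind_cols(tibble::tibble(snp_id = snp_id), out)
  out
}

#' TDT for a single SNP from explicit trio genotypes
#'
#' Genotypes are given as `"A/B"`-style allele pairs (order irrelevant,
#' missing = `"0/0"`). Trios with any missing member, or with a
#' Mendelian-inconsistent genotype configuration, are skipped. Each
#' heterozygous parent of a retained trio contributes exactly one
#' transmission observation.
#'
#' @param trio_genotypes Data frame with character columns `father`,
#'   `mother`, `offspring`.
#' @param minor_allele Single character; the allele whose transmissions are
#'   counted as `t`.
#' @return One-row tibble as in [tdt_from_counts()], plus `n_trios_used`.
#' @export
tdt_single <- function(trio_genotypes, minor_allele) {
  tg <- tibble::as_tibble(trio_genotypes)
  parse1 <- function(s) {
    a <- strsplit(s, "/", fixed = TRUE)
    ptr_assert(all(lengths(a) == 2), "genotypes must look like 'A/B'",
               "pathtrio_format_error")
    a
  }
  gf <- parse1(tg$father); gm <- parse1(tg$mother); gc <- parse1(tg$offspring)
  alleles <- setdiff(unique(unlist(c(gf, gm, gc))), "0")
  ptr_assert(minor_allele %in% alleles,
             sprintf("minor_allele '%s' not among observed alleles (%s)",
                     minor_allele, paste(alleles, collapse = ", ")))
  dose <- function(g) {
    miss <- vapply(g, function(x) any(x == "0"), logical(1))
    d <- vapply(g, function(x) sum(x == minor_allele), integer(1))
    ifelse(miss, NA_integer_, d)
  }
  res <- tdt_count_transmissions(dose(gf), dose(gm), dose(gc))
  out <- tdt_from_counts(res["t"], res["u"])
  out$n_trios_used <- as.integer(res["n_used"])
  out
}

# core transmission counting on minor-allele dosage vectors (one SNP).
# For parents with dosages (gf, gm) and offspring gc, the number of minor
# alleles transmitted by heterozygous parents is gc minus the forced
# contribution of minor-homozygous parents; the configuration is
# Mendelian-consistent iff that difference lies in [0, n_het_parents].
tdt_count_transmissions <- function(gf, gm, gc) {
  h2 <- (gf == 2) + (gm == 2)
  h1 <- (gf == 1) + (gm == 1)
  k <- gc - h2
  ok <- !is.na(gf) & !is.na(gm) & !is.na(gc) & k >= 0 & k <= h1
  c(t = sum(k[ok]), u = sum((h1 - k)[ok]), n_used = sum(ok))
}

#' Per-SNP TDT scan over all trios of a study
#'
#' Runs the Transmission Disequilibrium Test at every SNP, counting minor
#' alleles transmitted vs. untransmitted from heterozygous parents to
#' affected offspring. Trios with a missing member genotype at a SNP, or a
#' Mendelian-inconsistent configuration there, are skipped at that SNP only.
#' Monomorphic SNPs yield `n_informative = 0` and `p = 1`.
#'
#' @param study A [trio_study()] (normally after [apply_qc()]).
#' @return A tibble with one row per SNP in study order: `snp_id`, `chrom`,
#'   `pos`, `gene`, `func_class`, `minor_allele`, `maf`, `t`, `u`, `or`,
#'   `chi2`, `p`, `n_informative`.
#' @export
tdt_scan <- function(study) {
  ptr_assert(nrow(study$trios) > 0, "study contains no affected-offspring trios",
             "pathtrio_no_trios")
  freqs <- allele_frequencies(study, founders_only = TRUE)
  g <- dosage_minor(study, freqs)
  GF <- g[study$trios$father, , drop = FALSE]
  GM <- g[study$trios$mother, , drop = FALSE]
  GC <- g[study$trios$offspring, , drop = FALSE]
  h2 <- (GF == 2) + (GM == 2)
  h1 <- (GF == 1) + (GM == 1)
  k <- GC - h2
  ok <- !is.na(GF) & !is.na(GM) & !is.na(GC) & !is.na(k) & k >= 0 & k <= h1
  k[!ok] <- 0L
  h1[!ok] <- 0L
  t <- unname(colSums(k))
  u <- unname(colSums(h1 - k))
  out <- tdt_from_counts(t, u, snp_id = study$snps$snp_id)
  dplyr::bind_cols(
    study$snps[, c("snp_id", "chrom", "pos", "gene", "func_class")],
    tibble::tibble(minor_allele = freqs$minor_allele, maf = freqs$maf),
    out[, setdiff(names(out), "snp_id")]
  )
}

#' Write TDT results as TSV
#' @param results Tibble from [tdt_scan()].
#' @param path Output path.
#' @export
write_tdt_results <- function(results, path) {
  readr::write_tsv(results, path)
  invisible(results)
}
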