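# Small in-code fixture builders.

# A founders-only study from a dosage matrix (rows = founders, cols = SNPs).
founder_study <- function(geno, snp_id = sprintf("s%03d", seq_len(ncol(geno))),
                          chrom = "1") {
  n <- nrow(geno)
  individuals <- tibble::tibble(
    family_id = sprintf("F%04d", seq_len(n)), individual_id = "1",
    father_id = "0", mother_id = "0", sex = 1L, affection = 1L
  )
  snps <- tibble::tibble(
    snp_id = snp_id, chrom = chrom, pos = seq_along(snp_id) * 100L,
    allele_a = "A", allele_b = "B"
  )
  trio_study(individuals, snps, geno)
}

# A trio study from father/mother/offspring dosage matrices (one row per trio).
trio_dosage_study <- function(gf, gm, gc) {
  n <- nrow(gf)
  individuals <- tibble::tibble(
    family_id = rep(sprintf("F%04d", seq_len(n)), 3),
    individual_id = rep(c("1", "2", "3"), each = n),
    father_id = rep(c("0", "0", "1"), each = n),
    mother_id = rep(c("0", "0", "2"), each = n),
    sex = rep(c(1L, 2L, 1L), each = n),
    affection = rep(c(1L, 1L, 2L), each = n)
  )
  snps <- tibble::tibble(
    snp_id = sprintf("s%03d", seq_len(ncol(gf))), chrom = "1",
    pos = seq_len(ncol(gf)) * 100L, allele_a = "A", allele_b = "B"
  )
  trio_study(individuals, snps, rbind(gf, gm, gc))
}

# Write a tiny PED/MAP pair from character rows; returns the two paths.
write_ped_fixture <- function(ped_rows, map_rows,
                              dir = withr::local_tempdir(.local_envir = parent.frame())) {
  ped <- file.path(dir, "fix.ped")
  map <- file.path(dir, "fix.map")
  writeLines(ped_rows, ped)
  writeLines(map_rows, map)
  c(ped = ped, map = map)
}

# Minimal TDT-results-like tibble for permutation/enrichment tests.
fake_results <- function(snp_id, p, gene = NA_character_, func_class = "none") {
  tibble::tibble(
    snp_id = snp_id, chrom = "1", pos = seq_along(snp_id),
    gene = gene, func_class = func_class,
    minor_allele = "B", maf = 0.2,
    t = 1L, u = 1L, or = 1, chi2 = stats::qchisq(p, 1, lower.tail = FALSE),
    p = p, n_informative = 2L
  )
}
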