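#' Quality-control configuration
#'
#' Defaults follow standard trio-GWAS practice: minimum minor-allele
#' frequency 0.05, minimum per-SNP call rate 0.95, Hardy-Weinberg exact-test
#' p-value floor 1e-5, and `indep 50 5 2` sliding-window VIF pruning
#' (window of 50 SNPs, step 5, variance-inflation threshold 2).
#'
#' @param maf_min Minimum founder minor-allele frequency, in `[0, 0.5]`.
#' @param geno_min Minimum per-SNP genotype call rate, in `(0, 1]`.
#' @param hwe_p_min Minimum founder Hardy-Weinberg exact p-value.
#' @param vif_window,vif_step Window size and step, in SNPs.
#' @param vif_threshold VIF threshold `1/(1 - R^2)`, must be >= 1.
#' @return A `qc_config` list.
#' @export
qc_config <- function(maf_min = 0.05, geno_min = 0.95, hwe_p_min = 1e-5,
                      vif_window = 50, vif_step = 5, vif_threshold = 2) {
  ptr_assert(maf_min >= 0 && maf_min <= 0.5, "maf_min must be in [0, 0.5]")
  ptr_assert(geno_min > 0 && geno_min <= 1, "geno_min must be in (0, 1]")
  ptr_assert(hwe_p_min >= 0 && hwe_p_min <= 1, "hwe_p_min must be in [0, 1]")
  ptr_assert(vif_threshold >= 1, "vif_threshold must be >= 1")
  ptr_assert(vif_window >= 2 && vif_step >= 1, "vif_window >= 2 and vif_step >= 1 required")
  structure(list(maf_min = maf_min, geno_min = geno_min, hwe_p_min = hwe_p_min,
                 vif_window = as.integer(vif_window), vif_step = as.integer(vif_step),
                 vif_threshold = vif_threshold),
            class = "qc_config")
}

#' Per-SNP allele frequencies and call rates
#'
#' The minor allele is determined from observed allele frequencies (over
#' founders by default, the standard choice for trio data so that each
#' chromosome is counted once), never from file order. At an exact 0.5/0.5
#' tie `allele_b` is reported as the minor allele.
#'
#' @param study A [trio_study()].
#' @param founders_only Compute over founders only (default) or everyone.
#' @return Tibble with `snp_id`, `allele_a`, `allele_b`, `minor_allele`,
#'   `maf`, `call_rate`, `n_obs`. `maf` is `NA` for SNPs with no observed
#'   genotype (flagged for removal downstream).
#' @export
allele_frequencies <- function(study, founders_only = TRUE) {
  ptr_assert(nrow(study$snps) > 0 && nrow(study$individuals) > 0,
             "study is empty")
  sel <- if (founders_only) is_founder(study) else rep(TRUE, nrow(study$individuals))
  g <- study$geno[sel, , drop = FALSE]
  n_obs <- unname(colSums(!is.na(g)))
  freq_b <- unname(ifelse(n_obs > 0, colMeans(g, na.rm = TRUE) / 2, NA_real_))
  minor_is_b <- !is.na(freq_b) & freq_b <= 0.5
  tibble::tibble(
    snp_id = study$snps$snp_id,
    allele_a = study$snps$allele_a,
    allele_b = study$snps$allele_b,
    minor_allele = dplyr::case_when(
      is.na(freq_b) ~ NA_character_,
      minor_is_b ~ study$snps$allele_b,
      TRUE ~ study$snps$allele_a
    ),
    maf = ifelse(is.na(freq_b), NA_real_, pmin(freq_b, 1 - freq_b)),
    call_rate = n_obs / nrow(g),
    n_obs = as.integer(n_obs)
  )
}

# minor-allele dosage matrix (selected individuals x SNPs)
dosage_minor <- function(study, freqs = allele_frequencies(study, founders_only = TRUE)) {
  g <- study$geno
  flip <- !is.na(freqs$minor_allele) & freqs$minor_allele == freqs$allele_a &
    !is.na(freqs$allele_b)
  if (any(flip)) g[, flip] <- 2L - g[, flip, drop = FALSE]
  g
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test conditioning on the observed allele counts: the
#' p-value is the summed probability of all heterozygote counts no more
#' probable than the observed one. Vectorised over genotype-count triples.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (either homozygote may be the minor
#'   class; the test is symmetric under allele relabelling).
#' @return p-values in `(0, 1]`.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- cbind(n_aa, n_ab, n_bb)
  ptr_assert(all(n >= 0), "genotype counts must be non-negative")
  ptr_assert(all(rowSums(n) > 0), "all-zero genotype counts")
  vapply(seq_len(nrow(n)), function(i) {
    hwe_exact_one(n[i, 1], n[i, 2], n[i, 3])
  }, numeric(1))
}

# conditional distribution of the heterozygote count given allele totals,
# built by ratio recurrence and normalised; stable for founder counts used here
hwe_exact_one <- function(n_aa, n_ab, n_bb) {
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  n_rare <- min(n_a, n_b)
  if (n_rare == 0) return(1)
  h0 <- n_rare %% 2
  hs <- seq(h0, n_rare, by = 2)
  probs <- numeric(length(hs))
  probs[1] <- 1
  if (length(hs) > 1) {
    for (k in seq_len(length(hs) - 1)) {
      h <- hs[k]
      ratio <- ((n_a - h) / 2) * ((n_b - h) / 2) * 4 / ((h + 2) * (h + 1))
      probs[k + 1] <- probs[k] * ratio
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_ab, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

# founder genotype counts in minor-allele coding: columns n0, n1, n2
founder_geno_counts <- function(study, freqs) {
  g <- dosage_minor(study, freqs)[is_founder(study), , drop = FALSE]
  cbind(n0 = colSums(g == 0, na.rm = TRUE),
        n1 = colSums(g == 1, na.rm = TRUE),
        n2 = colSums(g == 2, na.rm = TRUE))
}

# pairwise-complete correlation via crossproducts (equivalent to
# cor(use = "pairwise.complete.obs") but BLAS-bound, which matters inside the
# sliding-window pruning loop)
fast_pairwise_cor <- function(X) {
  W <- (!is.na(X)) * 1
  X0 <- X
  X0[is.na(X0)] <- 0
  N <- crossprod(W)
  Sx <- crossprod(X0, W)
  Sxx <- crossprod(X0^2, W)
  Sxy <- crossprod(X0)
  covm <- Sxy - Sx * t(Sx) / N
  varx <- Sxx - Sx^2 / N
  r <- covm / sqrt(varx * t(varx))
  r[!is.finite(r)] <- NA_real_
  r
}

# Moore-Penrose pseudo-inverse via SVD (used only when a VIF window's
# correlation matrix is exactly singular)
pinv <- function(m, tol = 1e-10) {
  s <- svd(m)
  keep <- s$d > tol * s$d[1]
  if (!any(keep)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# VIFs for all columns of a correlation matrix; Inf when R^2 -> 1
window_vifs <- function(C) {
  inv <- tryCatch(solve(C), error = function(e) NULL)
  if (!is.null(inv)) {
    v <- unname(pmax(diag(inv), 1))
    # a numerically singular-but-invertible matrix can give huge finite VIFs;
    # that is fine, they exceed any sane threshold
    return(v)
  }
  k <- ncol(C)
  vapply(seq_len(k), function(i) {
    S <- C[-i, -i, drop = FALSE]
    r <- C[-i, i]
    r2 <- min(max(drop(crossprod(r, pinv(S) %*% r)), 0), 1)
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Sliding-window VIF-based LD pruning
#'
#' Within each window of `vif_window` SNPs (advanced by `vif_step`, per
#' chromosome), SNPs are removed one at a time — always the SNP with the
#' largest variance inflation factor `1/(1 - R^2)` against the other SNPs in
#' the window, ties broken by lowest index — until all remaining VIFs are at
#' or below `vif_threshold`. Removal is permanent across windows.
#' Correlations use pairwise-complete observations; monomorphic SNPs carry no
#' LD information and always pass. Windows at a chromosome end may be short;
#' windows with fewer than two polymorphic SNPs pass unchanged.
#'
#' @param study A [trio_study()].
#' @param cfg A [qc_config()].
#' @return Character vector of kept SNP IDs, in study order.
#' @export
vif_prune <- function(study, cfg = qc_config()) {
  freqs <- allele_frequencies(study, founders_only = TRUE)
  g <- dosage_minor(study, freqs)
  n_snp <- ncol(g)
  kept <- rep(TRUE, n_snp)
  poly <- !is.na(freqs$maf) & freqs$maf > 0
  for (chrom in unique(study$snps$chrom)) {
    idx <- which(study$snps$chrom == chrom)
    starts <- seq(1L, length(idx), by = cfg$vif_step)
    for (s in starts) {
      win <- idx[s:min(s + cfg$vif_window - 1L, length(idx))]
      repeat {
        active <- win[kept[win] & poly[win]]
        if (length(active) < 2) break
        C <- fast_pairwise_cor(g[, active, drop = FALSE])
        C[is.na(C)] <- 0
        diag(C) <- 1
        v <- window_vifs(C)
        if (max(v) <= cfg$vif_threshold) break
        kept[active[which.max(v)]] <- FALSE
      }
      if (s + cfg$vif_window - 1L >= length(idx)) break
    }
  }
  study$snps$snp_id[kept]
}

#' Apply the full QC cascade to a study
#'
#' Filters run in a fixed order — call rate (all individuals), minor-allele
#' frequency (founders), Hardy-Weinberg exact test (founders), VIF pruning —
#' and each SNP removal is attributed to the first filter that fails it.
#' SNPs with no observed genotypes have undefined MAF and are removed.
#'
#' @param study A [trio_study()].
#' @param cfg A [qc_config()].
#' @return A `qc_result`: list with the filtered `study` and a `report`
#'   tibble (`filter`, `snps_removed`, `snps_remaining`).
#' @export
apply_qc <- function(study, cfg = qc_config()) {
  n0 <- nrow(study$snps)
  report <- tibble::tibble(filter = character(), snps_removed = integer(),
                           snps_remaining = integer())
  note <- function(name, removed, remaining) {
    tibble::add_row(report, filter = name, snps_removed = as.integer(removed),
                    snps_remaining = as.integer(remaining))
  }
  check_nonempty <- function(ids) {
    if (length(ids) == 0) {
      ptr_abort("all SNPs removed by QC", "pathtrio_empty_study")
    }
  }

  # 1. call rate over all individuals
  cr <- allele_frequencies(study, founders_only = FALSE)$call_rate
  keep <- cr >= cfg$geno_min
  report <- note("call_rate", sum(!keep), sum(keep))
  check_nonempty(study$snps$snp_id[keep])
  study <- subset_snps(study, study$snps$snp_id[keep])

  # 2. founder MAF (undefined MAF counts as failing)
  freqs <- allele_frequencies(study, founders_only = TRUE)
  keep <- !is.na(freqs$maf) & freqs$maf >= cfg$maf_min
  report <- note("maf", sum(!keep), sum(keep))
  check_nonempty(study$snps$snp_id[keep])
  study <- subset_snps(study, study$snps$snp_id[keep])

  # 3. founder HWE exact test
  freqs <- allele_frequencies(study, founders_only = TRUE)
  cnt <- founder_geno_counts(study, freqs)
  hwe_p <- hwe_exact_p(cnt[, "n0"], cnt[, "n1"], cnt[, "n2"])
  keep <- hwe_p >= cfg$hwe_p_min
  report <- note("hwe", sum(!keep), sum(keep))
  check_nonempty(study$snps$snp_id[keep])
  study <- subset_snps(study, study$snps$snp_id[keep])

  # 4. VIF prune
  kept_ids <- vif_prune(study, cfg)
  report <- note("vif_prune", nrow(study$snps) - length(kept_ids), length(kept_ids))
  check_nonempty(kept_ids)
  study <- subset_snps(study, kept_ids)

  structure(list(study = study, report = report, n_input = n0),
            class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> ", x$n_input, " SNPs in, ",
      nrow(x$study$snps), " SNPs out\n", sep = "")
  print(x$report)
  invisible(x)
}
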