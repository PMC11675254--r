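test_that("allele frequencies match direct counting", {
  # 2 founders: AA and AB -> freq(B) = 1/4
  st <- founder_study(matrix(c(0L, 1L), 2, 1))
  af <- allele_frequencies(st)
  expect_equal(af$maf, 0.25)
  expect_equal(af$minor_allele, "B")
  expect_equal(af$call_rate, 1)

  # all heterozygous: maf 0.5, tie resolved to allele_b
  st <- founder_study(matrix(1L, 4, 1))
  af <- allele_frequencies(st)
  expect_equal(af$maf, 0.5)
  expect_equal(af$minor_allele, "B")
})

test_that("allele frequencies agree with a brute-force tally on a random fixture", {
  set.seed(42)
  g <- matrix(sample(c(0:2, NA), 100 * 20, replace = TRUE, prob = c(.4, .3, .25, .05)),
              100, 20)
  st <- founder_study(g)
  af <- allele_frequencies(st)
  for (j in seq_len(20)) {
    col <- g[, j]
    fb <- sum(col, na.rm = TRUE) / (2 * sum(!is.na(col)))
    expect_equal(af$maf[j], min(fb, 1 - fb))
    expect_equal(af$call_rate[j], mean(!is.na(col)))
  }
})

test_that("HWE exact test: monomorphic p = 1, allele-label symmetry, oracle match", {
  expect_equal(hwe_exact_p(10, 0, 0), 1)
  expect_equal(hwe_exact_p(0, 0, 7), 1)
  expect_error(hwe_exact_p(0, 0, 0), "all-zero")

  expect_identical(hwe_exact_p(57, 14, 50), hwe_exact_p(50, 14, 57))

  # full-enumeration oracle, >= 12 significant digits
  expect_equal(hwe_exact_p(57, 14, 50), oracle_hwe_p(57, 14, 50), tolerance = 1e-12)

  set.seed(7)
  for (rep in 1:50) {
    n <- sample(3:200, 1)
    n_ab <- sample(0:n, 1)
    n_aa <- sample(0:(n - n_ab), 1)
    n_bb <- n - n_ab - n_aa
    if (n_aa + n_ab + n_bb == 0) next
    expect_equal(hwe_exact_p(n_aa, n_ab, n_bb), oracle_hwe_p(n_aa, n_ab, n_bb),
                 tolerance = 1e-12,
                 info = sprintf("counts (%d,%d,%d)", n_aa, n_ab, n_bb))
  }
})

test_that("VIF pruning removes exactly one of two identical SNPs", {
  set.seed(11)
  x <- sample(0:2, 200, replace = TRUE, prob = c(.36, .48, .16))
  y <- sample(0:2, 200, replace = TRUE, prob = c(.36, .48, .16))
  st <- founder_study(cbind(x, x, y), snp_id = c("dup1", "dup2", "indep"))
  kept <- vif_prune(st, qc_config(vif_window = 3, vif_step = 1, vif_threshold = 2))
  expect_length(setdiff(c("dup1", "dup2"), kept), 1L)
  expect_true("indep" %in% kept)
  # documented tie-break: the lowest-index SNP of the tied pair goes first
  expect_false("dup1" %in% kept)
})

test_that("window VIF matches an independent least-squares fit", {
  set.seed(13)
  s1 <- rnorm(300)
  s2 <- rnorm(300)
  s3 <- s1 + rnorm(300, sd = 0.7)
  C <- stats::cor(cbind(s1, s2, s3))
  v <- pathtrio:::window_vifs(C)
  for (i in 1:3) {
    others <- setdiff(1:3, i)
    fit <- stats::lm(cbind(s1, s2, s3)[, i] ~ cbind(s1, s2, s3)[, others])
    expect_equal(v[i], 1 / (1 - summary(fit)$r.squared), tolerance = 1e-8)
  }
})

test_that("crossprod pairwise correlation equals cor(use = 'pairwise')", {
  set.seed(14)
  X <- matrix(rnorm(200 * 8), 200, 8)
  X[sample(length(X), 150)] <- NA
  expect_equal(pathtrio:::fast_pairwise_cor(X),
               suppressWarnings(stats::cor(X, use = "pairwise.complete.obs")),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("independent SNPs are essentially never pruned at threshold 2", {
  set.seed(19)
  g <- matrix(rbinom(500 * 100, 2, 0.3), 500, 100)
  st <- founder_study(g)
  kept <- vif_prune(st, qc_config())
  expect_gt(length(kept) / 100, 0.95)
})

test_that("QC filters run in order with per-filter attribution", {
  set.seed(23)
  base <- matrix(rbinom(200 * 6, 2, 0.3), 200, 6)
  colnames(base) <- NULL
  g <- base
  g[1:30, 1] <- NA                      # call rate 0.85 -> call_rate filter
  g[, 2] <- rbinom(200, 2, 0.01)        # maf ~0.01 -> maf filter
  g[, 3] <- 1L                          # all het -> HWE exact p ~ 0
  g[, 5] <- g[, 4]                      # duplicate -> VIF
  st <- founder_study(g, snp_id = sprintf("s%d", 1:6))
  res <- apply_qc(st, qc_config(vif_window = 6, vif_step = 1))
  expect_s3_class(res, "qc_result")
  expect_equal(res$report$filter, c("call_rate", "maf", "hwe", "vif_prune"))
  expect_equal(res$report$snps_removed, c(1L, 1L, 1L, 1L))
  expect_equal(res$report$snps_remaining, c(5L, 4L, 3L, 2L))
  expect_setequal(res$study$snps$snp_id, c("s5", "s6"))  # s4 lost to the VIF tie-break
})

test_that("a SNP failing both call rate and MAF is attributed to call rate", {
  set.seed(29)
  g <- matrix(rbinom(100 * 2, 2, 0.3), 100, 2)
  g[, 1] <- rbinom(100, 2, 0.01)   # low maf ...
  g[1:10, 1] <- NA                 # ... and call rate 0.90
  st <- founder_study(g)
  res <- apply_qc(st, qc_config(vif_window = 2, vif_step = 1))
  expect_equal(res$report$snps_removed[res$report$filter == "call_rate"], 1L)
  expect_equal(res$report$snps_removed[res$report$filter == "maf"], 0L)
})

test_that("lowering maf_min never removes more SNPs", {
  set.seed(31)
  g <- matrix(rbinom(300 * 40, 2, runif(40, 0.01, 0.5)[col(matrix(0, 300, 40))]), 300, 40)
  st <- founder_study(g)
  removed_at <- function(m) {
    r <- apply_qc(st, qc_config(maf_min = m, hwe_p_min = 0, vif_threshold = 1e9))$report
    r$snps_removed[r$filter == "maf"]
  }
  expect_lte(removed_at(0.01), removed_at(0.05))
  expect_lte(removed_at(0.05), removed_at(0.10))
})

test_that("removing every SNP raises an explicit empty-study error", {
  st <- founder_study(matrix(0L, 10, 2))  # monomorphic, maf 0
  expect_error(apply_qc(st, qc_config()), "all SNPs removed",
               class = "pathtrio_empty_study")
})
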