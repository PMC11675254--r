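test_that("null transmission is balanced within binomial error", {
  sim <- simulate_study(sim_config(n_trios = 2000, n_snps = 1, n_genes = 1,
                                   n_sets = 1, tau = 0.5, missing_rate = 0,
                                   seed = 101))
  r <- tdt_scan(sim$study)
  n <- r$t + r$u
  se <- sqrt(0.25 / n)
  expect_lt(abs(r$t / n - 0.5), 3 * se)
})

test_that("causal SNPs transmit the risk allele at rate tau", {
  sim <- simulate_study(sim_config(n_trios = 2000, n_snps = 1, n_genes = 1,
                                   n_sets = 1, causal_fraction = 1, tau = 0.6,
                                   missing_rate = 0, seed = 103))
  expect_true(all(sim$truth$is_causal))
  st <- sim$study
  # count transmissions of allele_b (the designated risk allele) directly
  freqs <- allele_frequencies(st)
  r <- tdt_scan(st)
  t_b <- if (freqs$minor_allele == st$snps$allele_b) r$t else r$u
  n <- r$t + r$u
  expect_lt(abs(t_b / n - 0.6), 3 * sqrt(0.24 / n))
})

test_that("missing_rate 0 yields a complete genotype matrix", {
  sim <- simulate_study(sim_config(n_trios = 50, n_snps = 30, n_genes = 6,
                                   n_sets = 2, missing_rate = 0, seed = 107))
  expect_false(anyNA(sim$study$geno))
  sim2 <- simulate_study(sim_config(n_trios = 200, n_snps = 30, n_genes = 6,
                                    n_sets = 2, missing_rate = 0.1, seed = 107))
  expect_lt(abs(mean(is.na(sim2$study$geno)) - 0.1), 0.01)
})

test_that("founder genotypes are HWE-consistent and recover the drawn MAFs", {
  sim <- simulate_study(sim_config(n_trios = 300, n_snps = 1000, n_genes = 100,
                                   n_sets = 10, tau = 0.5, missing_rate = 0,
                                   seed = 109))
  st <- sim$study
  freqs <- allele_frequencies(st)
  cnt <- pathtrio:::founder_geno_counts(st, freqs)
  hp <- hwe_exact_p(cnt[, "n0"], cnt[, "n1"], cnt[, "n2"])
  # exact-test p-values behave like a (conservative, discrete) null sample
  expect_gt(mean(hp < 0.05), 0.0)
  expect_lt(mean(hp < 0.05), 0.08)
  expect_lt(mean(hp < 0.001), 0.005)

  # realized founder frequency of the risk allele regresses on the drawn MAF
  # with slope ~ 1
  realized <- colMeans(st$geno[is_founder(st), , drop = FALSE], na.rm = TRUE) / 2
  fit <- stats::lm(realized ~ sim$truth$maf)
  expect_lt(abs(stats::coef(fit)[2] - 1), 0.05)
  expect_lt(abs(stats::coef(fit)[1]), 0.02)
})

test_that("the generator seed makes byte-identical PED/MAP files", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_trios = 20, n_snps = 15, n_genes = 3, n_sets = 1, seed = 113)
  p1 <- write_sim_study(simulate_study(cfg), dir, "a")
  p2 <- write_sim_study(simulate_study(cfg), dir, "b")
  expect_identical(readLines(p1["ped"]), readLines(p2["ped"]))
  expect_identical(readLines(p1["map"]), readLines(p2["map"]))
  expect_identical(readLines(p1["gmt"]), readLines(p2["gmt"]))
})

test_that("study pairs share architecture but not genotypes", {
  cfg <- sim_config(n_trios = 200, n_snps = 200, n_genes = 20, n_sets = 2,
                    tau = 0.6, causal_fraction = 0.5, missing_rate = 0, seed = 127)
  pair <- simulate_pair(cfg, subset_fraction = 1)
  expect_identical(pair$investigation$truth, pair$replication$truth)
  gi <- pair$investigation$study$geno
  gr <- pair$replication$study$geno
  # centred genotypes of arbitrarily-paired individuals are uncorrelated
  q <- pair$investigation$truth$snp_id  # same panel, same column order
  centred_i <- sweep(gi, 2, colMeans(gi))
  centred_r <- sweep(gr, 2, colMeans(gr))
  expect_lt(abs(stats::cor(as.vector(centred_i), as.vector(centred_r))), 0.01)
})

test_that("the replication panel is a stated-fraction subset", {
  cfg <- sim_config(n_trios = 20, n_snps = 500, n_genes = 50, n_sets = 5, seed = 131)
  pair <- simulate_pair(cfg, subset_fraction = 0.46)
  inv_ids <- pair$investigation$study$snps$snp_id
  rep_ids <- pair$replication$study$snps$snp_id
  expect_true(all(rep_ids %in% inv_ids))
  expect_equal(length(rep_ids), round(0.46 * 500))
  # pathway availability drops roughly in proportion
  path_ids <- pair$investigation$truth$snp_id[pair$investigation$truth$set_id == "set01"]
  frac <- mean(path_ids %in% rep_ids)
  expect_gt(frac, 0.33)
  expect_lt(frac, 0.59)
  expect_error(simulate_pair(cfg, subset_fraction = 0), "subset_fraction")
})

test_that("class probabilities and causal bookkeeping hold", {
  cfg <- sim_config(n_trios = 10, n_snps = 2000, n_genes = 100, n_sets = 10,
                    causal_set_id = "set03", causal_fraction = 0.5, tau = 0.55,
                    seed = 137)
  sim <- simulate_study(cfg)
  tr <- sim$truth
  expect_true(all(tr$set_id[tr$is_causal] == "set03"))
  n_set3 <- sum(tr$set_id == "set03")
  expect_equal(sum(tr$is_causal), floor(0.5 * n_set3))
  expect_true(all(tr$tau[tr$is_causal] == 0.55))
  expect_true(all(tr$tau[!tr$is_causal] == 0.5))
  expect_lt(abs(mean(tr$func_class == "missense") - 0.05), 0.02)
  expect_error(simulate_study(sim_config(n_snps = 50, n_genes = 10, n_sets = 2,
                                         causal_set_id = "nope")),
               "causal_set_id")
})
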