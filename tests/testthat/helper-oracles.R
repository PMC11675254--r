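# Independent oracles used to cross-check the package's statistics.
# These deliberately use different algorithms from the implementation:
# brute-force enumeration and direct log-factorial formulas.

# Brute-force TDT for one SNP: enumerate, per trio, which parental allele
# could have been transmitted, skipping missing and Mendelian-impossible
# configurations. Dosages count the minor allele.
oracle_tdt_counts <- function(gf, gm, gc) {
  alleles_of <- function(g) switch(as.character(g), "0" = c(0, 0), "1" = c(0, 1), "2" = c(1, 1))
  t <- 0L; u <- 0L; used <- 0L
  for (i in seq_along(gf)) {
    if (anyNA(c(gf[i], gm[i], gc[i]))) next
    fa <- alleles_of(gf[i]); ma <- alleles_of(gm[i]); ca <- alleles_of(gc[i])
    found <- NULL
    for (x in unique(fa)) for (y in unique(ma)) {
      if (setequal_multiset(c(x, y), ca)) { found <- c(x, y); break }
    }
    if (is.null(found)) next  # Mendelian error
    used <- used + 1L
    if (gf[i] == 1) { t <- t + found[1]; u <- u + 1L - found[1] }
    if (gm[i] == 1) { t <- t + found[2]; u <- u + 1L - found[2] }
  }
  c(t = t, u = u, n_used = used)
}

setequal_multiset <- function(a, b) identical(sort(a), sort(b))

# Hardy-Weinberg exact p by direct summation of the conditional probability
# P(n_ab | allele counts) = n! / (n_aa! n_ab! n_bb!) * 2^n_ab * n_a! n_b! / (2n)!
oracle_hwe_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  lp <- function(h) {
    haa <- (n_a - h) / 2; hbb <- (n_b - h) / 2
    lfactorial(n) - lfactorial(haa) - lfactorial(h) - lfactorial(hbb) +
      h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }
  hs <- seq(min(n_a, n_b) %% 2, min(n_a, n_b), by = 2)
  if (length(hs) == 0) return(1)
  probs <- exp(vapply(hs, lp, numeric(1)))
  p_obs <- probs[match(n_ab, hs)]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-10)]))
}

# Upper-tail hypergeometric by exhaustive enumeration of all draws of
# query_size genes from the universe (small universes only).
oracle_hyper_p <- function(set_genes, query_size, universe, observed_overlap) {
  draws <- utils::combn(universe, query_size, simplify = FALSE)
  mean(vapply(draws, function(d) sum(d %in% set_genes) >= observed_overlap, logical(1)))
}

# Exceedance by exhaustive enumeration of all same-size SNP subsets of the
# universe (no class matching; use all-"none" universes).
oracle_exceedance <- function(p_by_snp, set_size, obs_count, level) {
  subsets <- utils::combn(names(p_by_snp), set_size, simplify = FALSE)
  mean(vapply(subsets, function(s) sum(p_by_snp[s] < level) >= obs_count, logical(1)))
}
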