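#' Simulation configuration for synthetic trio studies
#'
#' Describes a synthetic affected-offspring trio study: founders in
#' Hardy-Weinberg equilibrium at per-SNP minor-allele frequencies drawn from
#' `maf_range`, offspring genotypes generated by Mendelian transmission, and
#' excess transmission of the risk (minor) allele injected only at "causal"
#' SNPs inside a designated gene set. Ascertainment is modelled purely as
#' transmission distortion — all offspring are labelled affected — because
#' the TDT's non-centrality depends only on the transmission probability.
#'
#' @param n_trios Number of father-mother-offspring trios.
#' @param n_snps Number of SNPs (partitioned contiguously across genes).
#' @param n_genes Number of genes (partitioned contiguously across sets).
#' @param n_sets Number of gene sets in the generated GMT.
#' @param causal_set_id Which set carries the causal SNPs (default the first,
#'   `"set01"`).
#' @param causal_fraction Fraction of the causal set's SNPs given distortion.
#' @param tau Transmission probability of the risk allele from heterozygous
#'   parents at causal SNPs; 0.5 is the null, values above 0.5 induce TDT
#'   signal. Must be in `[0.5, 1)`.
#' @param maf_range Range of per-SNP minor-allele frequencies (subset of
#'   `(0, 0.5]`).
#' @param missing_rate Per-genotype missingness probability.
#' @param class_probs Probabilities of the functional classes
#'   `missense`/`splice`/`none`, assigned independently of causality so that
#'   class matching in permutations is exercised without confounding.
#' @param seed Optional integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_trios = 500, n_snps = 1000, n_genes = 100, n_sets = 10,
                       causal_set_id = "set01", causal_fraction = 0.5,
                       tau = 0.5, maf_range = c(0.05, 0.5), missing_rate = 0.02,
                       class_probs = c(missense = 0.05, splice = 0.01, none = 0.94),
                       seed = NULL) {
  ptr_assert(tau >= 0.5 && tau < 1, "tau must be in [0.5, 1)")
  ptr_assert(missing_rate >= 0 && missing_rate < 1, "missing_rate must be in [0, 1)")
  ptr_assert(abs(sum(class_probs) - 1) < 1e-8, "class_probs must sum to 1")
  ptr_assert(all(c("missense", "splice", "none") %in% names(class_probs)),
             "class_probs must name missense, splice, none")
  ptr_assert(maf_range[1] > 0 && maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
             "maf_range must be within (0, 0.5]")
  ptr_assert(causal_fraction >= 0 && causal_fraction <= 1,
             "causal_fraction must be in [0, 1]")
  ptr_assert(n_genes <= n_snps && n_sets <= n_genes,
             "need n_sets <= n_genes <= n_snps")
  structure(list(n_trios = as.integer(n_trios), n_snps = as.integer(n_snps),
                 n_genes = as.integer(n_genes), n_sets = as.integer(n_sets),
                 causal_set_id = causal_set_id, causal_fraction = causal_fraction,
                 tau = tau, maf_range = maf_range, missing_rate = missing_rate,
                 class_probs = class_probs, seed = seed),
            class = "sim_config")
}

# fixed causal architecture: SNP -> gene -> set, MAFs, classes, causal flags.
# Consumes the current RNG stream.
build_architecture <- function(cfg) {
  n <- cfg$n_snps
  gene <- sprintf("gene%04d", sort(rep_len(seq_len(cfg$n_genes), n)))
  gene_set <- sprintf("set%02d", sort(rep_len(seq_len(cfg$n_sets), cfg$n_genes)))
  names(gene_set) <- sprintf("gene%04d", seq_len(cfg$n_genes))
  set_of_snp <- unname(gene_set[gene])
  ptr_assert(cfg$causal_set_id %in% gene_set,
             sprintf("causal_set_id '%s' not among generated sets", cfg$causal_set_id))
  pair <- replicate(n, sample(c("A", "C", "G", "T"), 2))
  arch <- tibble::tibble(
    snp_id = sprintf("rs%06d", seq_len(n)),
    chrom = "1",
    pos = 10000L * seq_len(n),
    allele_a = pair[1, ],
    allele_b = pair[2, ],
    maf = runif(n, cfg$maf_range[1], cfg$maf_range[2]),
    gene = gene,
    set_id = set_of_snp,
    func_class = sample(names(cfg$class_probs), n, replace = TRUE,
                        prob = cfg$class_probs)
  )
  in_causal <- which(arch$set_id == cfg$causal_set_id)
  n_causal <- floor(cfg$causal_fraction * length(in_causal))
  causal <- rep(FALSE, n)
  if (n_causal > 0) causal[sample(in_causal, n_causal)] <- TRUE
  arch$is_causal <- causal
  arch$tau <- ifelse(causal, cfg$tau, 0.5)
  arch
}

# genotype sampling given an architecture; consumes the RNG stream.
# geno counts the allele_b (= risk/minor-by-design) allele.
sample_genotypes <- function(arch, n_trios, missing_rate) {
  n_snp <- nrow(arch)
  q <- arch$maf
  # founders in HWE: dosage ~ Binomial(2, q)
  GF <- matrix(rbinom(n_trios * n_snp, 2, rep(q, each = n_trios)), n_trios, n_snp)
  GM <- matrix(rbinom(n_trios * n_snp, 2, rep(q, each = n_trios)), n_trios, n_snp)
  # each parent transmits one allele; heterozygotes transmit the risk allele
  # with probability tau (0.5 off the causal set), homozygotes deterministically
  TAU <- matrix(rep(arch$tau, each = n_trios), n_trios, n_snp)
  TF <- (GF == 2) + (GF == 1) * matrix(rbinom(n_trios * n_snp, 1, TAU), n_trios, n_snp)
  TM <- (GM == 2) + (GM == 1) * matrix(rbinom(n_trios * n_snp, 1, TAU), n_trios, n_snp)
  GC <- TF + TM
  geno <- rbind(GF, GM, GC)
  if (missing_rate > 0) {
    geno[runif(length(geno)) < missing_rate] <- NA_integer_
  }
  fam <- sprintf("F%05d", seq_len(n_trios))
  individuals <- tibble::tibble(
    family_id = rep(fam, 3),
    individual_id = rep(c("1", "2", "3"), each = n_trios),
    father_id = rep(c("0", "0", "1"), each = n_trios),
    mother_id = rep(c("0", "0", "2"), each = n_trios),
    sex = c(rep(1L, n_trios), rep(2L, n_trios),
            sample(1:2, n_trios, replace = TRUE)),
    affection = rep(c(1L, 1L, 2L), each = n_trios)
  )
  snps <- arch[, c("snp_id", "chrom", "pos", "allele_a", "allele_b",
                   "gene", "func_class")]
  trio_study(individuals, snps, geno)
}

# GMT from an architecture's gene -> set mapping
arch_gene_sets <- function(arch) {
  by_set <- split(arch$gene, arch$set_id)
  gene_set_db(lapply(by_set, unique),
              descriptions = paste("synthetic gene set", names(by_set)))
}

#' Simulate one synthetic trio study
#'
#' Generates a [trio_study()] together with its annotation table, GMT gene
#' sets, and a truth record listing which SNPs carry transmission
#' distortion. All randomness is taken from R's RNG; pass `cfg$seed` for
#' reproducibility.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_study` list: `study`, `annotation`, `gene_sets`, `truth`
#'   (tibble `snp_id`, `gene`, `set_id`, `func_class`, `maf`, `is_causal`, `tau`),
#'   `config`.
#' @export
simulate_study <- function(cfg = sim_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  arch <- build_architecture(cfg)
  study <- sample_genotypes(arch, cfg$n_trios, cfg$missing_rate)
  structure(list(
    study = study,
    annotation = arch[, c("snp_id", "gene", "func_class")],
    gene_sets = arch_gene_sets(arch),
    truth = arch[, c("snp_id", "gene", "set_id", "func_class", "maf", "is_causal", "tau")],
    config = cfg
  ), class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("<sim_study> tau = ", x$config$tau, ", ",
      sum(x$truth$is_causal), " causal SNPs in ", x$config$causal_set_id, "\n",
      sep = "")
  print(x$study)
  invisible(x)
}

#' Simulate an investigation/replication study pair
#'
#' Both studies share one causal architecture (same SNP parameters, genes,
#' sets and causal flags) but have independent families; the replication
#' study's SNP panel is a random subset of the investigation panel,
#' mimicking the incomplete overlap of two genotyping arrays. The default
#' subset fraction of 0.46 mirrors the availability drop typical when a
#' pathway's SNPs are looked up on a second array.
#'
#' @param cfg_inv A [sim_config()] for the investigation sample.
#' @param subset_fraction Fraction of the SNP panel present in the
#'   replication sample, in `(0, 1]`.
#' @param n_trios_rep Number of replication trios (default: same as
#'   investigation).
#' @return List with `investigation` and `replication` (both `sim_study`,
#'   sharing `truth` restricted to each panel).
#' @export
simulate_pair <- function(cfg_inv = sim_config(), subset_fraction = 0.46,
                          n_trios_rep = cfg_inv$n_trios) {
  ptr_assert(subset_fraction > 0 && subset_fraction <= 1,
             "subset_fraction must be in (0, 1]")
  if (!is.null(cfg_inv$seed)) set.seed(cfg_inv$seed)
  arch <- build_architecture(cfg_inv)
  inv_study <- sample_genotypes(arch, cfg_inv$n_trios, cfg_inv$missing_rate)
  keep <- sort(sample.int(nrow(arch), round(subset_fraction * nrow(arch))))
  arch_rep <- arch[keep, , drop = FALSE]
  rep_study <- sample_genotypes(arch_rep, as.integer(n_trios_rep),
                                cfg_inv$missing_rate)
  wrap <- function(study, a, cfg) {
    structure(list(
      study = study,
      annotation = a[, c("snp_id", "gene", "func_class")],
      gene_sets = arch_gene_sets(arch),  # sets defined on the full panel
      truth = a[, c("snp_id", "gene", "set_id", "func_class", "maf", "is_causal", "tau")],
      config = cfg
    ), class = "sim_study")
  }
  cfg_rep <- cfg_inv
  cfg_rep$n_trios <- as.integer(n_trios_rep)
  list(investigation = wrap(inv_study, arch, cfg_inv),
       replication = wrap(rep_study, arch_rep, cfg_rep))
}

#' Write a simulated study's files (PED/MAP, annotation TSV, GMT, truth TSV)
#'
#' @param sim A `sim_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the named vector of paths written.
#' @export
write_sim_study <- function(sim, dir, prefix = "study") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ped = file.path(dir, paste0(prefix, ".ped")),
    map = file.path(dir, paste0(prefix, ".map")),
    annotation = file.path(dir, paste0(prefix, "_annotation.tsv")),
    gmt = file.path(dir, paste0(prefix, "_sets.gmt")),
    truth = file.path(dir, paste0(prefix, "_truth.tsv"))
  )
  write_ped_map(sim$study, paths["ped"], paths["map"])
  write_annotation(sim$annotation, paths["annotation"])
  write_gmt(sim$gene_sets, paths["gmt"])
  readr::write_tsv(sim$truth, paths["truth"])
  invisible(paths)
}
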