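#' Permutation-test configuration
#'
#' Controls the annotation-matched permutation null. The one-sided
#' acceptance thresholds default to half the nominal significance levels
#' (0.025 for the 0.05-level count, 0.005 for the 0.01-level count), because
#' only an excess — never a deficit — of significant SNPs counts as
#' evidence for pathway enrichment.
#'
#' @param n_perm Number of permuted SNP sets (default 1e6; scale down for
#'   exploratory runs).
#' @param match_classes Match each draw to the tested set's functional-class
#'   composition (missense / splice / none)? Default `TRUE`; when a class is
#'   exhausted in the universe, set `FALSE` to fall back to size-only
#'   matching.
#' @param seed Optional integer seed; when given, results are bit-reproducible.
#' @param relax_matching When `TRUE`, fall back to size-only matching (with
#'   a warning) if some functional class has too few SNPs left in the
#'   universe; when `FALSE` (default) that situation is an error.
#' @param alpha_05,alpha_01 One-sided acceptance thresholds for the
#'   0.05-level and 0.01-level exceedance fractions, each in `(0, 0.5)`.
#' @return A `perm_config` list.
#' @export
perm_config <- function(n_perm = 1e6, match_classes = TRUE, seed = NULL,
                        alpha_05 = 0.025, alpha_01 = 0.005,
                        relax_matching = FALSE) {
  ptr_assert(n_perm >= 1, "n_perm must be >= 1")
  ptr_assert(alpha_05 > 0 && alpha_05 < 0.5 && alpha_01 > 0 && alpha_01 < 0.5,
             "thresholds must be in (0, 0.5)")
  structure(list(n_perm = as.integer(n_perm), match_classes = isTRUE(match_classes),
                 seed = seed, alpha_05 = alpha_05, alpha_01 = alpha_01,
                 relax_matching = isTRUE(relax_matching)),
            class = "perm_config")
}

#' Draw one annotation-matched random SNP set
#'
#' Samples SNPs uniformly without replacement, separately within each
#' functional class, to match a target class composition. The universe
#' passed in should already exclude the tested pathway's own SNPs, so the
#' null is not contaminated by the tested signal.
#'
#' @param universe Tibble with columns `snp_id`, `func_class`.
#' @param target_class_counts Named integer vector over
#'   `missense`/`splice`/`none` (absent names count as 0).
#' @return Character vector of sampled SNP IDs.
#' @export
draw_matched_set <- function(universe, target_class_counts) {
  out <- character(0)
  for (cls in names(target_class_counts)) {
    k <- target_class_counts[[cls]]
    if (k == 0) next
    pool <- universe$snp_id[universe$func_class == cls]
    if (length(pool) < k) {
      ptr_abort(sprintf(
        "cannot draw %d SNPs of class '%s': only %d available in the universe",
        k, cls, length(pool)), "pathtrio_infeasible_matching")
    }
    out <- c(out, pool[sample.int(length(pool), k)])
  }
  out
}

#' Matched-permutation test of pathway enrichment
#'
#' Counts the tested SNP set's significant associations at the 0.05 and 0.01
#' levels, then draws `n_perm` random SNP sets from the rest of the panel —
#' matched to the tested set's size and functional-class composition — and
#' records the fraction of draws with at least as many significant SNPs
#' (the exceedance fraction, a one-sided permutation p-value analogue).
#' The enrichment hypothesis (H1) is accepted only when both exceedance
#' fractions fall below their one-sided thresholds; otherwise the null (H0)
#' stands. A tested set with zero significant SNPs has exceedance 1 by
#' construction and yields H0.
#'
#' @param results Tibble from [tdt_scan()] (needs `snp_id`, `func_class`, `p`).
#' @param pathway_snp_ids SNP IDs of the tested set; those absent from
#'   `results` are ignored.
#' @param cfg A [perm_config()].
#' @param levels The two nominal significance levels (fixed at
#'   `c(0.05, 0.01)` for the standard analysis).
#' @return A `perm_verdict`: list with `observed_count_05/_01`,
#'   `exceed_frac_05/_01`, `mc_se_05/_01` (Monte-Carlo standard errors of
#'   the exceedance estimates), `decision` (`"H1"`/`"H0"`), `n_perm`,
#'   `alpha_05/_01`, `n_set`, `class_counts`, `seed`.
#' @export
permutation_test <- function(results, pathway_snp_ids, cfg = perm_config(),
                             levels = c(0.05, 0.01)) {
  in_path <- results$snp_id %in% pathway_snp_ids
  ptr_assert(any(in_path), "no tested-pathway SNPs present in the results")
  universe <- results[!in_path, c("snp_id", "func_class")]
  ptr_assert(nrow(universe) > 0, "empty permutation universe")

  obs05 <- sum(results$p[in_path] < levels[1])
  obs01 <- sum(results$p[in_path] < levels[2])
  cls <- factor(results$func_class[in_path], levels = c("missense", "splice", "none"))
  target <- setNames(as.integer(table(cls)), levels(cls))
  size_only <- !cfg$match_classes
  if (cfg$match_classes && isTRUE(cfg$relax_matching)) {
    short <- vapply(names(target), function(cl) {
      sum(universe$func_class == cl) < target[[cl]]
    }, logical(1))
    if (any(short)) {
      warn(sprintf("class '%s' exhausted in the universe; falling back to size-only matching",
                   names(target)[short][1]))
      size_only <- TRUE
    }
  }
  if (size_only) {
    target <- c(missense = 0L, splice = 0L, none = sum(in_path))
    universe$func_class <- "none"
  }
  # feasibility check up front so the error names the class
  draw_pools <- lapply(names(target), function(cl) {
    k <- target[[cl]]
    pool <- which(universe$func_class == cl)
    if (length(pool) < k) {
      ptr_abort(sprintf(
        "cannot draw %d SNPs of class '%s': only %d available in the universe",
        k, cl, length(pool)), "pathtrio_infeasible_matching")
    }
    list(k = k, pool = pool)
  })

  sig05 <- results$p[!in_path] < levels[1]
  sig01 <- results$p[!in_path] < levels[2]
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ge05 <- 0L
  ge01 <- 0L
  for (i in seq_len(cfg$n_perm)) {
    c05 <- 0L
    c01 <- 0L
    for (dp in draw_pools) {
      if (dp$k == 0L) next
      take <- dp$pool[sample.int(length(dp$pool), dp$k)]
      c05 <- c05 + sum(sig05[take])
      c01 <- c01 + sum(sig01[take])
    }
    if (c05 >= obs05) ge05 <- ge05 + 1L
    if (c01 >= obs01) ge01 <- ge01 + 1L
  }
  ex05 <- ge05 / cfg$n_perm
  ex01 <- ge01 / cfg$n_perm
  structure(list(
    observed_count_05 = obs05, observed_count_01 = obs01,
    exceed_frac_05 = ex05, exceed_frac_01 = ex01,
    mc_se_05 = sqrt(ex05 * (1 - ex05) / cfg$n_perm),
    mc_se_01 = sqrt(ex01 * (1 - ex01) / cfg$n_perm),
    decision = if (ex05 < cfg$alpha_05 && ex01 < cfg$alpha_01) "H1" else "H0",
    n_perm = cfg$n_perm, alpha_05 = cfg$alpha_05, alpha_01 = cfg$alpha_01,
    n_set = sum(in_path), class_counts = target, seed = cfg$seed
  ), class = "perm_verdict")
}

#' @export
print.perm_verdict <- function(x, ...) {
  cat("<perm_verdict> ", x$decision, " (", x$n_perm, " permutations, set of ",
      x$n_set, " SNPs)\n", sep = "")
  cat(sprintf("  p<0.05: observed %d, exceedance %.4f (MC se %.4f) vs %.3f\n",
              x$observed_count_05, x$exceed_frac_05, x$mc_se_05, x$alpha_05))
  cat(sprintf("  p<0.01: observed %d, exceedance %.4f (MC se %.4f) vs %.3f\n",
              x$observed_count_01, x$exceed_frac_01, x$mc_se_01, x$alpha_01))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.perm_verdict <- function(x, ...) {
  tibble::tibble(
    level = c(0.05, 0.01),
    observed_count = c(x$observed_count_05, x$observed_count_01),
    exceed_frac = c(x$exceed_frac_05, x$exceed_frac_01),
    mc_se = c(x$mc_se_05, x$mc_se_01),
    threshold = c(x$alpha_05, x$alpha_01),
    decision = x$decision
  )
}

#' @exportS3Method generics::glance
glance.perm_verdict <- function(x, ...) {
  tibble::tibble(
    n_set = x$n_set, n_perm = x$n_perm,
    exceed_frac_05 = x$exceed_frac_05, exceed_frac_01 = x$exceed_frac_01,
    decision = x$decision
  )
}

#' Combine the two samples' permutation verdicts
#'
#' The pathway is declared replicated only when the enrichment hypothesis is
#' accepted in both the investigation and the replication sample.
#'
#' @param investigation_verdict,replication_verdict `perm_verdict` objects.
#' @return `"replicated"` or `"not_replicated"`.
#' @export
decide_replication <- function(investigation_verdict, replication_verdict) {
  if (investigation_verdict$decision == "H1" &&
      replication_verdict$decision == "H1") "replicated" else "not_replicated"
}
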