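---
title: "Two-phase molecular-pathway analysis of trio GWAS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase molecular-pathway analysis of trio GWAS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathtrio)
```

## The analysis in one paragraph

pathtrio implements a two-phase, family-based pathway analysis for disorders
studied through affected-offspring trios. Phase 1 takes an *investigation*
trio sample, runs the Transmission Disequilibrium Test (TDT) at every SNP
after standard quality control, collects the genes harbouring the strongest
associations ("genelist1"), and asks which gene sets (e.g. GO terms) are
over-represented among them; the winning set is the *index pathway* and its
full gene list is "genelist2". Phase 2 takes an independent *replication*
trio sample and asks whether the index pathway's SNPs are significant there
more often than chance predicts — summarised by a within-pathway
*prevalence* statistic — and whether that excess survives comparison with an
annotation-matched permutation null. The pathway is declared *replicated*
only when the permutation test accepts the enrichment hypothesis in both
samples.

## The TDT and its assumptions

For each SNP, every heterozygous parent of an affected offspring contributes
one transmission observation: the minor allele was either transmitted
($T$) or not ($U$). The statistic is

$$\chi^2 = \frac{(T-U)^2}{T+U},$$

referred to a 1-df chi-square distribution (two-sided), with odds ratio
$\mathrm{OR} = T/U$. Homozygous parents are uninformative. Because the test
conditions on parental genotypes, it is immune to population stratification
— which is why the inflation screen below is a sanity check rather than a
correction step. Trios with a missing member genotype at a SNP, or a
Mendelian-impossible configuration there, are skipped *at that SNP only*;
discarding the whole trio would throw away valid information at every other
SNP. The chi-square approximation (rather than an exact binomial) matches
standard GWAS tooling; `n_informative` is reported per SNP so users can
filter low-information markers if they wish.

Internally the transmission count is computed algebraically: with parental
minor-allele dosages $(g_f, g_m)$ and offspring dosage $g_c$, the minor
alleles transmitted by heterozygous parents equal
$g_c - \#\{\text{parents with dosage } 2\}$, and the configuration is
Mendelian-consistent exactly when that quantity lies in
$[0, \#\text{het parents}]$. The test suite checks this against a
brute-force per-trio enumeration oracle.

## Quality control

`apply_qc()` runs, in a fixed order, with each removal attributed to the
first filter that fails:

1. **call rate** ≥ 0.95 (all individuals);
2. **minor-allele frequency** ≥ 0.05, computed on founders so each
   chromosome is counted once;
3. **Hardy–Weinberg exact test** on founders, removing p < 1e-5. The exact
   test conditions on allele counts and sums the probabilities of all
   heterozygote counts no more probable than the observed one (two-sided
   "no more probable" definition). It is computed by a ratio recurrence with
   final normalisation, which is numerically stable at the founder counts a
   trio study produces; the suite verifies agreement with direct
   log-factorial enumeration to 12 significant digits up to 200 founders.
4. **VIF-based LD pruning** with a sliding window of 50 SNPs advanced by 5,
   removing SNPs until every variance inflation factor
   $\mathrm{VIF} = 1/(1-R^2)$ is ≤ 2. Within a window, removal is iterative
   (largest VIF first, ties broken by lowest index — this makes pruning
   deterministic) and permanent across windows. Correlations use
   pairwise-complete observations, computed with a crossproduct formulation
   so that pruning large panels stays fast. A window whose correlation
   matrix is exactly singular is handled through a pseudo-inverse, which
   assigns infinite VIF to perfectly collinear SNPs. Monomorphic SNPs carry
   no LD information and always pass; windows at a chromosome end may be
   short.

HWE on founders only is the standard choice for trio data (offspring of the
same families are not independent draws from the population). The filter
order itself is a convention; the report table makes the bookkeeping
auditable and testable.

## Inflation screen

`genomic_lambda()` is the median-based genomic inflation factor: the median
observed 1-df statistic over informative SNPs divided by
`qchisq(0.5, 1)` ≈ 0.455. The median (rather than the mean or a regression
fit) is robust to a minority of true signals, which is exactly the situation
a successful scan produces; note that a *concentrated* true signal still
lifts the median slightly, so λ should be read jointly with the QQ plot.
`qq_coordinates()` pairs the $i$-th smallest p-value with the uniform
quantile $i/(n+1)$ — the $+1$ avoids $-\log_{10}(0)$ at the extreme ranks.

## From association to pathway

`build_genelist1()` keeps the unique genes harbouring at least one SNP with
$p < 0.001$. That threshold intentionally prioritises strong candidates
while leaving enough genes for a set-level test.

`enrich_gene_sets()` computes, per gene set, the upper-tail hypergeometric
probability $P(X \ge \text{overlap})$ of the observed overlap between the
query and the set when drawing $|\text{query}|$ genes from the universe,
adjusted across sets by Benjamini–Hochberg. Two deliberate choices:

* **The universe is the genes represented on the post-QC SNP panel**, not
  the genome. Array-bound gene lists tested against a genome-wide universe
  look spuriously enriched for well-covered pathways; an array-bound
  universe removes that coverage bias.
* **Gene sets are flat lists** (GMT input). No GO-DAG propagation or
  evidence-code filtering is attempted; if the input GMT was produced by a
  tool that propagates annotations, that structure is inherited as-is.

`select_index_pathway()` takes the single set with the smallest adjusted p
below α = 0.05 (ties: larger overlap, then lexicographic set id — both
documented and exercised by tests). Its SNP universe is *every* study SNP in
its genes, not only the sub-threshold ones: the replication question is
about the pathway as a whole, not about re-testing the discovery SNPs.
When nothing passes, the pipeline stops cleanly with a distinct
"no index pathway" outcome rather than an error.

## Replication: prevalence and the matched permutation null

`select_replication_snps()` carries the index pathway into the replication
sample, keeping SNPs that are (i) in the pathway, (ii) present on the
replication panel, and (iii) direction-concordant (OR on the same side of 1
in both samples). An infinite OR (all transmissions) is risk-directional; an
OR exactly 1 or undefined is non-directional and excluded. An optional
`strict_p_threshold` additionally requires the investigation p-value below a
cutoff (e.g. 0.001); it is off by default because the membership +
availability + direction rule is the one whose arithmetic is
self-consistent at realistic pathway sizes.

`prevalence()` is the fraction of selected SNPs significant at a nominal
level in the replication sample. Under no enrichment its expectation is the
level itself, so the *relative excess*
$100\,(\text{prevalence} - \text{level})/\text{level}$ reads directly as
"percent more significant SNPs than chance".

`permutation_test()` draws random SNP sets from the rest of the panel,
matched to the tested set's size *and* functional-class composition
(missense / splice / unannotated), and reports the exceedance fraction: the
proportion of draws with **at least** as many significant SNPs as observed,
at the 0.05 and 0.01 levels. Matching on annotation classes keeps the null
honest when coding variation is both enriched in curated pathways and more
likely to associate. Three design points:

* Draws exclude the tested pathway's own SNPs; sampling the complement
  avoids contaminating the null with the tested signal.
* The acceptance thresholds are **halved** — 0.025 for the 0.05-level count
  and 0.005 for the 0.01-level count — because only an excess (never a
  deficit) of significant SNPs counts as evidence; the test is one-sided by
  construction.
* The "same or more" rule makes the exceedance fraction a valid, slightly
  conservative permutation p-value: because the significant-SNP count is
  discrete, $P(\text{exceedance} < \alpha) \le \alpha$ with strict
  inequality in practice. On fully null synthetic studies the measured rate
  of 0.05-level exceedance below 0.025 is around 1.5–2.5%, the conservative
  side of nominal — this is a property of the procedure, visible in the
  calibration runs, not a defect.

Enrichment (H1) is accepted only when *both* exceedance fractions fall below
their thresholds; `decide_replication()` declares the pathway replicated
only when H1 holds in both samples. A fixed `n_perm` with Monte-Carlo
standard errors in the output replaces any adaptive stopping rule: adaptive
"run until stable" schemes bias exceedance estimates near thresholds and are
not reproducible. Exceedance estimates are bit-reproducible given
(`seed`, `n_perm`, universe order). By default an exhausted functional class
(more class-$c$ SNPs in the tested set than in the remaining universe) is an
error naming the class; `relax_matching = TRUE` falls back to size-only
matching with a warning, which is the pragmatic choice in simulation loops
where a rare class occasionally concentrates in the tested set.

## What the simulator emulates — and what it does not

`simulate_study()` generates affected-offspring trios with:

* founders in Hardy–Weinberg equilibrium at per-SNP MAFs drawn uniformly
  from `maf_range` (default 0.05–0.5, matching the post-QC regime of a
  GWAS array);
* Mendelian transmission, except that heterozygous parents transmit the
  designated risk allele with probability τ at "causal" SNPs
  (τ = 0.5 is the exact null; the TDT's non-centrality is
  $(2\tau-1)^2(T+U)$, so ascertainment is modelled purely as transmission
  distortion and no liability-threshold disease model is needed);
* causal SNPs confined to a designated gene set (`causal_set_id`, a fraction
  `causal_fraction` of its SNPs), with SNPs partitioned contiguously across
  genes and genes across sets;
* functional classes drawn independently of causality (default 5% missense,
  1% splice, 94% unannotated — a realistic array composition), so
  class-matched permutation is exercised without confounding;
* per-genotype missingness at `missing_rate` (default 2%, which keeps
  per-SNP call rates comfortably above the 0.95 QC floor while still
  exercising the missing-data paths).

`simulate_pair()` shares one causal architecture between an investigation
and a replication study but draws independent families, and restricts the
replication panel to a random subset of SNPs (default fraction 0.46,
mirroring the availability drop seen when one array's pathway SNPs are
looked up on another).

Deliberately **not** modelled: linkage disequilibrium (SNPs are independent;
a duplicated-column construction exercises VIF pruning in tests instead),
population stratification, X-chromosome inheritance, de novo variation, and
genotyping error beyond missingness. Consequently, passing tests demonstrate
the statistical machinery — calibration, power, bookkeeping — under the
analysis's own assumptions; they do not demonstrate robustness to LD
structure or stratification in real data, where the TDT's conditioning and
the QC stages carry that burden.

## Problem sizes and calibration evidence

The test suite runs everything at desk scale, chosen to keep the full suite
within a few minutes while leaving the Monte-Carlo bands meaningful:

* type-I calibration: 1000 null studies (100 trios, 500 SNPs, a 50-SNP
  designated pathway, 500 permutations each); the rate of 0.05-level
  exceedance below 0.025 must sit within 3 binomial standard errors of 2.5%;
* power / recovery: 50 simulated study pairs at τ = 0.6,
  `causal_fraction` 0.5, 500 trios per sample on a 1200-SNP panel
  (12 sets × 100 SNPs); the injected set must be selected as index pathway
  and the end-to-end decision must be "replicated" in the majority of seeds;
* monotonicity: the H1 rate increases over τ ∈ {0.50, 0.55, 0.60}
  (200 replicates each at 200 trios);
* oracle equivalence: TDT vs per-trio enumeration, hypergeometric vs
  exhaustive draws, exceedance vs exhaustive $\binom{6}{2}$ subsets, HWE vs
  direct enumeration — combinatorial checks to 12 significant digits,
  sampled checks within 3 Monte-Carlo standard errors.

`scripts/acceptance.R` repeats the calibration measurement at a larger
fixed size (1000 studies of 200 trios × 2000 SNPs with a 100-SNP pathway,
2000 permutations) and writes the resulting rate as JSON.

## Known limitations

* The hypergeometric test treats genes as exchangeable; gene length and SNP
  density per gene are not modelled (the SNP-level permutation in Phase 2 is
  the compensating control, since it matches on SNP counts, not genes).
* The prevalence statistic's "expected" value is the nominal level; under
  strong discreteness of TDT p-values (few informative trios) the true null
  prevalence sits slightly below the level, making the relative excess mildly
  conservative.
* Multiplex families are handled per affected offspring (each offspring with
  two genotyped parents is one trio); siblings are not down-weighted.
* No proxy-SNP lookup: an index-pathway SNP absent from the replication
  panel is simply unavailable, as in the availability filter.
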