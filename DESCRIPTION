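Package: pathtrio
Title: Two-Phase Molecular-Pathway Analysis of Trio GWAS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for family-based (trio) genome-wide association
    analysis with pathway-level replication. Reads Plink-style text PED/MAP
    trio genotypes, applies standard quality control (minor-allele frequency,
    call rate, Hardy-Weinberg exact test on founders, VIF-based LD pruning),
    runs the Transmission Disequilibrium Test per SNP, screens for genomic
    inflation (lambda, QQ coordinates), tests gene sets for hypergeometric
    over-representation among associated genes to define an index pathway,
    and judges replication of that pathway in an independent trio sample via
    a within-pathway prevalence statistic and an annotation-matched
    permutation null. Includes a trio-genotype simulator with transmission
    distortion concentrated in a designated causal gene set, so the full
    two-phase analysis runs end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
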