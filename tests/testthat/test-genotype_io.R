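test_that("a minimal PED/MAP pair parses into one trio with two SNPs", {
  paths <- write_ped_fixture(
    c("FAM1 1 0 0 1 1 A A G G",
      "FAM1 2 0 0 2 1 A C G T",
      "FAM1 3 1 2 1 2 A C G G"),
    c("1 rs1 0 1000", "1 rs2 0 2000")
  )
  st <- read_ped_map(paths["ped"], paths["map"])
  expect_s3_class(st, "trio_study")
  expect_equal(unname(study_dim(st)), c(3L, 2L, 1L))
  expect_equal(st$snps$snp_id, c("rs1", "rs2"))
  expect_equal(st$snps$pos, c(1000L, 2000L))
  # rs1: allele_a = A (first observed), allele_b = C
  expect_equal(st$geno[, "rs1"], c("FAM1:1" = 0L, "FAM1:2" = 1L, "FAM1:3" = 1L))
  expect_equal(st$trios$offspring_id, "3")
})

test_that("'0 0' encodes a missing genotype and the individual is retained", {
  paths <- write_ped_fixture(
    c("FAM1 1 0 0 1 1 0 0",
      "FAM1 2 0 0 2 1 A C",
      "FAM1 3 1 2 1 2 A A"),
    "1 rs1 0 1000"
  )
  st <- read_ped_map(paths["ped"], paths["map"])
  expect_true(is.na(st$geno["FAM1:1", "rs1"]))
  expect_equal(nrow(st$individuals), 3L)
  expect_equal(nrow(st$trios), 1L)
})

test_that("an offspring whose father is absent from the family forms no trio", {
  paths <- write_ped_fixture(
    c("FAM1 2 0 0 2 1 A C",
      "FAM1 3 9 2 1 2 A A"),  # father '9' not in FAM1
    "1 rs1 0 1000"
  )
  st <- read_ped_map(paths["ped"], paths["map"])
  expect_equal(nrow(st$trios), 0L)
  expect_equal(nrow(st$individuals), 2L)
})

test_that("format errors name the offending line; duplicate IDs are rejected", {
  paths <- write_ped_fixture(
    c("FAM1 1 0 0 1 1 A A",
      "FAM1 2 0 0 2 1 A"),
    "1 rs1 0 1000"
  )
  expect_error(read_ped_map(paths["ped"], paths["map"]),
               "PED line 2", class = "pathtrio_format_error")

  paths <- write_ped_fixture(
    c("FAM1 1 0 0 1 1 A A",
      "FAM1 1 0 0 2 1 A C"),
    "1 rs1 0 1000"
  )
  expect_error(read_ped_map(paths["ped"], paths["map"]),
               "duplicate individual", class = "pathtrio_format_error")

  paths <- write_ped_fixture("FAM1 1 0 0 1 1 A A", "1 rs1 0 1000 extra")
  expect_error(read_ped_map(paths["ped"], paths["map"]),
               "MAP line 1", class = "pathtrio_format_error")
})

test_that("write_ped_map round-trips bit-exactly on a canonical fixture", {
  ped_rows <- c("FAM1 1 0 0 1 1 A C G G",
                "FAM1 2 0 0 2 1 A A 0 0",
                "FAM1 3 1 2 1 2 A A G T")
  paths <- write_ped_fixture(ped_rows, c("1\trs1\t0\t1000", "2\trs2\t0\t2000"))
  st <- read_ped_map(paths["ped"], paths["map"])
  dir <- withr::local_tempdir()
  out_ped <- file.path(dir, "out.ped")
  out_map <- file.path(dir, "out.map")
  write_ped_map(st, out_ped, out_map)
  expect_identical(readLines(out_ped), ped_rows)
  expect_identical(readLines(out_map), c("1\trs1\t0\t1000", "2\trs2\t0\t2000"))
  # and a second read reproduces the same study
  st2 <- read_ped_map(out_ped, out_map)
  expect_identical(st2$geno, st$geno)
  expect_identical(st2$individuals, st$individuals)
  expect_identical(st2$snps, st$snps)
})

test_that("trio derivation is independent of PED row order", {
  rows <- c("FAM1 1 0 0 1 1 A C",
            "FAM1 2 0 0 2 1 A A",
            "FAM1 3 1 2 1 2 A C",
            "FAM2 1 0 0 1 1 C C",
            "FAM2 2 0 0 2 1 A C",
            "FAM2 3 1 2 2 2 A C")
  map <- "1 rs1 0 1000"
  st1 <- read_ped_map(write_ped_fixture(rows, map)["ped"],
                      write_ped_fixture(rows, map)["map"])
  set.seed(1)
  st2 <- read_ped_map(write_ped_fixture(sample(rows), map)["ped"],
                      write_ped_fixture(rows, map)["map"])
  key <- function(s) paste(s$trios$family_id, s$trios$offspring_id)
  expect_setequal(key(st1), key(st2))
  expect_identical(key(st2), sort(key(st2)))  # sorted output
})

test_that("annotation TSV parses, validates tokens, and rejects duplicates", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "ann.tsv")
  writeLines(c("snp_id\tgene\tfunc_class", "rs1\tPCDH9\tMISSENSE", "rs2\tTRPC4\tnone"), f)
  ann <- read_annotation(f)
  expect_equal(ann$func_class, c("missense", "none"))
  expect_equal(ann$gene[ann$snp_id == "rs1"], "PCDH9")

  writeLines("snp_id\tgene\tfunc_class", f)
  expect_equal(nrow(read_annotation(f)), 0L)

  writeLines(c("snp_id\tgene\tfunc_class", "rs1\tPCDH9\tnonsense"), f)
  expect_error(read_annotation(f), "missense, splice, none",
               class = "pathtrio_format_error")

  writeLines(c("snp_id\tgene\tfunc_class", "rs1\tPCDH9\tmissense", "rs1\tTRPC4\tnone"), f)
  expect_error(read_annotation(f), "duplicate snp_id",
               class = "pathtrio_format_error")
})

test_that("annotate_study fills gaps with gene = NA, func_class = 'none'", {
  st <- founder_study(matrix(c(0L, 1L, 2L, 0L), 2, 2), snp_id = c("rs1", "rs2"))
  ann <- tibble::tibble(snp_id = "rs1", gene = "PCDH9", func_class = "splice")
  st <- annotate_study(st, ann)
  expect_equal(st$snps$gene, c("PCDH9", NA))
  expect_equal(st$snps$func_class, c("splice", "none"))
})

test_that("GMT parsing de-duplicates genes and enforces set_id uniqueness", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "sets.gmt")
  writeLines("GO:0007417\tCNS development\tPCDH9\tTRPC4\tTMPRSS4", f)
  db <- read_gmt(f)
  expect_equal(db$n_genes, 3L)
  expect_setequal(db$genes[[1]], c("PCDH9", "TRPC4", "TMPRSS4"))

  writeLines("GO:1\tdesc\tA\tA\tB", f)
  expect_equal(read_gmt(f)$genes[[1]], c("A", "B"))

  writeLines(c("GO:1\tdesc\tA", "GO:1\tdesc\tB"), f)
  expect_error(read_gmt(f), "duplicate set_id", class = "pathtrio_format_error")

  writeLines("GO:1\tdesc", f)
  expect_error(read_gmt(f), "at least 3", class = "pathtrio_format_error")

  db <- gene_set_db(list(s1 = c("A", "B")))
  f2 <- file.path(dir, "roundtrip.gmt")
  write_gmt(db, f2)
  expect_equal(read_gmt(f2)$genes[[1]], c("A", "B"))
})
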