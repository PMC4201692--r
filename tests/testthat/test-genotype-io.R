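# PLINK and final-report text round-trips and encoding conventions.

test_that("PED alleles map onto dosages and missing codes", {
  td <- withr::local_tempdir()
  writeLines(c("1 L1 0 1000000 A G", "1 L2 0 2000000 C T"),
             file.path(td, "x.map"))
  writeLines("FAM S1 0 0 1 -9 A A C T", file.path(td, "x.ped"))
  res <- read_plink(file.path(td, "x.ped"), file.path(td, "x.map"))
  expect_equal(unname(res$genotypes$calls[1, ]), c(0L, 1L))
  expect_equal(res$pedigree$sex, "MALE")

  writeLines("FAM S1 0 0 2 -9 0 0 T T", file.path(td, "x.ped"))
  res <- read_plink(file.path(td, "x.ped"), file.path(td, "x.map"))
  expect_true(is.na(res$genotypes$calls[1, 1]))
  expect_equal(unname(res$genotypes$calls[1, 2]), 2L)
  expect_equal(res$pedigree$sex, "FEMALE")
})

test_that("chromosome 30 is accepted as an alias for X", {
  td <- withr::local_tempdir()
  writeLines("30 L1 0 1000000 A G", file.path(td, "x.map"))
  writeLines("FAM S1 0 0 0 -9 A G", file.path(td, "x.ped"))
  res <- read_plink(file.path(td, "x.ped"), file.path(td, "x.map"))
  expect_equal(res$genotypes$loci$chromosome, "X")
})

test_that("ragged or corrupt PED rows fail with a line reference", {
  td <- withr::local_tempdir()
  writeLines("1 L1 0 1000000 A G", file.path(td, "x.map"))
  writeLines("FAM S1 0 0 1 -9 A", file.path(td, "x.ped"))
  expect_error(read_plink(file.path(td, "x.ped"), file.path(td, "x.map")),
               "line 1")
  writeLines("FAM S1 0 0 1 -9 A Z", file.path(td, "x.ped"))
  expect_error(read_plink(file.path(td, "x.ped"), file.path(td, "x.map")),
               "allele")
})

test_that("write_plink / read_plink round-trips random matrices", {
  td <- withr::local_tempdir()
  gm <- random_gm(20, 50, seed = 3)
  ped <- pedigree_table(rownames(gm$calls),
                        sex = rep(c("MALE", "FEMALE"), 10))
  write_plink(gm, ped, file.path(td, "rt"))
  back <- read_plink(file.path(td, "rt.ped"), file.path(td, "rt.map"))
  expect_identical(back$genotypes$calls, gm$calls)
  expect_identical(back$genotypes$loci$locus_id, gm$loci$locus_id)
  expect_identical(back$genotypes$loci$chromosome, gm$loci$chromosome)
  expect_identical(back$pedigree$sex, ped$sex)

  # degenerate: zero samples still yields a full map
  empty <- genotype_matrix(matrix(NA_integer_, 0, 50), gm$loci, character(0))
  write_plink(empty, NULL, file.path(td, "empty"))
  expect_equal(length(readLines(file.path(td, "empty.ped"))), 0)
  expect_equal(length(readLines(file.path(td, "empty.map"))), 50)
})

test_that("final report parses calls with quality and round-trips", {
  td <- withr::local_tempdir()
  p <- file.path(td, "fr.txt")
  writeLines(c("[Header]", "junk\tstuff", "[Data]",
               "SNP Name\tSample ID\tAllele1 - AB\tAllele2 - AB\tGC Score",
               "snp1\ts1\tA\tB\t0.87",
               "snp2\ts1\t-\t-\t",
               "snp1\ts2\tB\tB\t0.55",
               "snp2\ts2\tA\tA\t0.91"), p)
  gm <- read_final_report(p)
  expect_equal(unname(gm$calls["s1", ]), c(1L, NA))
  expect_equal(unname(gm$calls["s2", ]), c(2L, 0L))
  expect_equal(unname(gm$quality["s1", "snp1"]), 0.87)

  p2 <- file.path(td, "fr2.txt")
  write_final_report(gm, p2)
  back <- read_final_report(p2)
  expect_identical(back$calls, gm$calls)
  expect_equal(back$quality, gm$quality)
})

test_that("final report with unknown columns names what it found", {
  td <- withr::local_tempdir()
  p <- file.path(td, "bad.txt")
  writeLines(c("Foo\tBar", "x\ty"), p)
  expect_error(read_final_report(p), "columns present")
})

test_that("pedigree TSV round-trips and rejects bad structure", {
  td <- withr::local_tempdir()
  ped <- pedigree_table(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"),
                        c("MALE", "FEMALE", "UNKNOWN"))
  p <- file.path(td, "ped.tsv")
  write_pedigree(ped, p)
  back <- read_pedigree(p)
  expect_identical(as.data.frame(back), as.data.frame(ped))

  expect_error(pedigree_table("A", sire_id = "A"), "own parent")
  expect_error(pedigree_table(c("A", "B"), sire_id = c("Z", NA)),
               "absent")
})
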