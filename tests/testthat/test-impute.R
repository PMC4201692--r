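# Mendelian checks, family rules, haplotype library and imputation.

test_that("Mendelian impossibilities are flagged, possibles are not", {
  loci <- tiny_loci(3)
  # sire HOM_A, dam HOM_A, embryo HET -> flagged
  expect_true(find_mendelian_inconsistencies(
    c(1L, 1L, 1L), c(0L, 0L, 1L), c(0L, 2L, 1L), loci)[1])
  # sire HOM_A, dam HOM_B, embryo HOM_A -> flagged (must be HET)
  expect_true(find_mendelian_inconsistencies(
    c(0L, 0L, 0L), c(0L, 0L, 0L), c(2L, 0L, 0L), loci)[1])
  # HET x HET parents: any embryo genotype possible
  fl <- find_mendelian_inconsistencies(
    c(0L, 1L, 2L), rep(1L, 3), rep(1L, 3), loci)
  expect_equal(sum(fl), 0)
  # missing parents impose no constraint
  fl2 <- find_mendelian_inconsistencies(
    c(0L, 1L, 2L), NULL, NULL, loci)
  expect_equal(sum(fl2), 0)
})

test_that("X inconsistencies are sex-aware", {
  loci <- tiny_loci(0, 3)
  # male embryo: heterozygous X impossible; allele must come from dam
  expect_true(find_mendelian_inconsistencies(
    c(1L, 0L, 0L), NULL, c(0L, 0L, 0L), loci, "MALE")[1])
  expect_true(find_mendelian_inconsistencies(
    c(0L, 2L, 0L), NULL, c(0L, 0L, 0L), loci, "MALE")[2])
  # female embryo: sire's coded X homozygote is his single allele, so
  # sire A x dam B forces a HET daughter
  expect_false(find_mendelian_inconsistencies(
    c(1L, 1L, 1L), c(0L, 0L, 0L), c(2L, 2L, 2L), loci, "FEMALE")[3])
  expect_true(find_mendelian_inconsistencies(
    c(2L, 2L, 2L), c(0L, 0L, 0L), c(2L, 2L, 2L), loci, "FEMALE")[3])
  expect_true(find_mendelian_inconsistencies(
    c(0L, 0L, 0L), c(2L, 2L, 2L), c(1L, 1L, 1L), loci, "FEMALE")[1])
})

test_that("correction blanks flags and a re-run finds nothing", {
  loci <- tiny_loci(4)
  embryo <- c(1L, 2L, 0L, 1L)
  sire <- c(0L, 0L, 0L, 1L)
  dam <- c(0L, 1L, 0L, 1L)
  fl <- find_mendelian_inconsistencies(embryo, sire, dam, loci)
  cc <- correct_inconsistencies(embryo, fl)
  expect_equal(cc$n_corrected, sum(fl))
  fl2 <- find_mendelian_inconsistencies(cc$calls, sire, dam, loci)
  expect_equal(sum(fl2), 0)
})

test_that("family rules fill forced genotypes and record half-constraints", {
  loci <- tiny_loci(4)
  embryo <- rep(NA_integer_, 4)
  sire <- c(0L, 1L, 0L, 2L)
  dam <- c(2L, 1L, NA, 2L)
  fam <- impute_family(embryo, sire, dam, loci)
  expect_equal(fam$calls[1], 1L)            # HOM_A x HOM_B -> HET
  expect_true(is.na(fam$calls[2]))          # HET x HET unresolvable
  expect_true(is.na(fam$calls[3]))          # one parent unknown
  expect_equal(fam$pat_allele[3], 0L)       # but one allele fixed
  expect_equal(fam$calls[4], 4L - 2L)       # HOM_B x HOM_B -> HOM_B
})

test_that("library phasing is deterministic and accurate on mosaics", {
  sc <- small_cohort(seed = 31, n_loci = 1200, n_trios = 10,
                     n_founders = 40, n_autosomes = 4)
  lib1 <- build_library(sc$founders)
  lib2 <- build_library(sc$founders)
  expect_identical(lib1$h1, lib2$h1)
  expect_identical(lib1$h2, lib2$h2)
  # haplotypes recompose the genotypes
  expect_identical(unname(lib1$h1 + lib1$h2),
                   unname(sc$founders$genotypes$calls) + 0L)
  pa <- phase_accuracy(lib1, sc$founders$haplotypes$h1,
                       sc$founders$haplotypes$h2)
  expect_gt(pa$het_accuracy, 0.9)

  # a fully homozygous sample phases trivially
  loci <- tiny_loci(6)
  hom <- genotype_matrix(rbind(c(0L, 2L, 0L, 2L, 0L, 0L),
                               c(0L, 1L, 1L, 2L, 0L, 1L)), loci)
  lib3 <- build_library(hom)
  expect_equal(unname(lib3$h1[1, ]), c(0, 1, 0, 1, 0, 0))
  expect_identical(lib3$h1[1, ], lib3$h2[1, ])
})

test_that("population imputation completes and honours a unanimous library", {
  loci <- tiny_loci(5)
  h <- matrix(c(1L, 1L, 1L, 0L, 1L), 4, 5, byrow = TRUE)
  lib <- structure(list(h1 = h[1:2, ], h2 = h[3:4, ],
                        resolved = matrix(TRUE, 2, 5),
                        freqs = colMeans(h), loci = loci,
                        sample_ids = c("a", "b"),
                        window_lengths = c(4, 2, 1), min_match = 0.9),
                   class = "haplotype_library")
  calls <- c(2L, NA, 2L, 0L, 2L)
  out <- impute_population(calls, lib, loci)
  expect_false(anyNA(out))
  expect_equal(out[2], 2L)      # all library haplotypes carry B there

  # constraint composition: one allele fixed A, library unanimous B
  out2 <- impute_population(c(NA, NA, 2L, 0L, 2L), lib, loci,
                            pat_allele = c(0L, 0L, NA, NA, NA))
  expect_equal(out2[2], 1L)
})

test_that("correct-and-impute repairs a degraded trio cohort end to end", {
  sc <- small_cohort(seed = 32, n_loci = 1500, n_trios = 15,
                     n_founders = 34, n_autosomes = 5)
  fo <- sc$founders; tr <- sc$trios
  truth <- tr$embryos
  ped <- tr$pedigree
  prof <- calibrate_wga_profile(mean(truth$calls == 1L))
  inj <- inject_wga_errors(truth, prof, seed = 33)
  lib <- build_library(fo)
  fg <- fo$genotypes$calls
  n_bad_in <- 0; n_bad_out <- 0
  for (i in seq_len(nrow(truth$calls))) {
    sex <- ped$sex[match(rownames(truth$calls)[i], ped$individual_id)]
    res <- correct_and_impute(inj$degraded$calls[i, ], tr$sires[i],
                              tr$dams[i], lib, fo$loci, embryo_sex = sex,
                              error_rate = inflate_channel(prof))
    expect_false(anyNA(res$calls))
    # repaired genotypes stay Mendelian-consistent with the parents
    fl <- find_mendelian_inconsistencies(
      res$calls, fg[match(tr$sires[i], rownames(fg)), ],
      fg[match(tr$dams[i], rownames(fg)), ], fo$loci, sex)
    expect_equal(sum(fl), 0)
    n_bad_in <- n_bad_in +
      sum(inj$degraded$calls[i, ] != truth$calls[i, ], na.rm = TRUE)
    n_bad_out <- n_bad_out + sum(res$calls != truth$calls[i, ])
  }
  # the bulk of the errors is repaired even at this small cohort size
  # (phasing information is much weaker than at the full design scale)
  expect_lt(n_bad_out, 0.5 * n_bad_in)
})

test_that("population-only imputation is weaker than trio-informed repair", {
  sc <- small_cohort(seed = 34, n_loci = 1000, n_trios = 8,
                     n_founders = 20, n_autosomes = 4)
  fo <- sc$founders; tr <- sc$trios
  truth <- tr$embryos
  ped <- tr$pedigree
  prof <- calibrate_wga_profile(mean(truth$calls == 1L))
  inj <- inject_wga_errors(truth, prof, seed = 35)
  lib <- build_library(fo)
  err_trio <- 0; err_pop <- 0
  for (i in seq_len(nrow(truth$calls))) {
    sex <- ped$sex[match(rownames(truth$calls)[i], ped$individual_id)]
    with_p <- correct_and_impute(inj$degraded$calls[i, ], tr$sires[i],
                                 tr$dams[i], lib, fo$loci, embryo_sex = sex)
    no_p <- correct_and_impute(inj$degraded$calls[i, ], NA, NA, lib,
                               fo$loci, embryo_sex = sex)
    expect_false(anyNA(no_p$calls))
    err_trio <- err_trio + sum(with_p$calls != truth$calls[i, ])
    err_pop <- err_pop + sum(no_p$calls != truth$calls[i, ])
  }
  expect_lte(err_trio, err_pop)
})

test_that("pedigree inbreeding is zero for outbred trios and positive for inbreds", {
  ped <- pedigree_table(c("S", "D", "E"), c(NA, NA, "S"), c(NA, NA, "D"),
                        c("MALE", "FEMALE", "FEMALE"))
  expect_equal(pedigree_inbreeding("E", ped), 0)
  # sire-daughter mating: F = 0.25
  ped2 <- pedigree_table(c("S", "D", "X", "Z"),
                         c(NA, NA, "S", "S"), c(NA, NA, "D", "X"),
                         c("MALE", "FEMALE", "FEMALE", "FEMALE"))
  expect_equal(pedigree_inbreeding("Z", ped2), 0.25)
})

test_that("imputation report: genomic F near zero at HWE, missing rate zero", {
  sc <- small_cohort(seed = 36, n_loci = 1500, n_trios = 10,
                     n_founders = 60)
  fo <- sc$founders
  lib <- build_library(fo)
  rep_ <- imputation_report(fo$genotypes, fo$genotypes, fo$pedigree,
                            lib$freqs)
  expect_true(all(rep_$final_missing_rate == 0))
  expect_true(all(rep_$pedigree_inbreeding == 0))
  # founders are drawn at the library frequencies: mean genomic F ~ 0
  expect_lt(abs(mean(rep_$genomic_inbreeding)), 0.1)
})
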