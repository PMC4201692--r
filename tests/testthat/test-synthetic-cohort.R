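# Founder/trio simulation: frequencies, LD, inheritance, X coding.

test_that("config validation rejects inconsistent settings", {
  expect_error(cohort_config(n_loci = 100, seed = 1, maf_low = 0.6),
               "maf")
  expect_error(cohort_config(n_loci = 100, n_founders = 10, n_trios = 20,
                             seed = 1), "n_founders")
  expect_error(cohort_config(n_loci = 100), "seed")
})

test_that("allele frequencies follow the configured uniform (large pool)", {
  cc <- cohort_config(n_loci = 3000, n_autosomes = 5, n_founders = 300,
                      n_trios = 2, n_ancestral = 400, seed = 17)
  fo <- simulate_founders(cc)
  # drawn spectrum is exactly uniform
  ks1 <- suppressWarnings(ks.test(fo$freqs, "punif", 0.05, 0.5))
  expect_gt(ks1$p.value, 0.01)
  # realized frequencies track the drawn ones
  realized <- colMeans(fo$genotypes$calls) / 2
  expect_gt(cor(realized, fo$freqs), 0.9)
})

test_that("heterozygosity approaches 1/2 at fixed MAF 0.5", {
  cc <- cohort_config(n_loci = 2000, n_autosomes = 5, n_founders = 200,
                      n_trios = 2, maf_low = 0.5, maf_high = 0.5,
                      n_ancestral = 500, seed = 18)
  fo <- simulate_founders(cc)
  expect_lt(abs(mean(fo$genotypes$calls == 1L) - 0.5), 0.02)
})

test_that("ld_rho 0 gives linkage equilibrium; 0.9 gives strong adjacency", {
  adj_cor <- function(rho, seed) {
    cc <- cohort_config(n_loci = 1200, n_autosomes = 2, n_founders = 200,
                        n_trios = 2, ld_rho = rho, seed = seed)
    fo <- simulate_founders(cc)
    j <- which(fo$loci$chromosome == "1")
    g <- fo$genotypes$calls
    mean(vapply(seq_len(length(j) - 1), function(k)
      suppressWarnings(cor(g[, j[k]], g[, j[k + 1]])), 0), na.rm = TRUE)
  }
  c0 <- adj_cor(0, 19)
  c9 <- adj_cor(0.9, 20)
  expect_lt(abs(c0), 0.05)
  expect_gt(c9, c0 + 0.3)
})

test_that("trio inheritance is forced where parents are homozygous", {
  sc <- small_cohort(seed = 21)
  fo <- sc$founders; tr <- sc$trios
  fg <- fo$genotypes$calls
  auto <- !is_x_locus(fo$loci)
  for (i in c(1, 4)) {
    s <- fg[match(tr$sires[i], rownames(fg)), ]
    d <- fg[match(tr$dams[i], rownames(fg)), ]
    e <- tr$embryos$calls[i, ]
    forced_het <- auto & ((s == 0 & d == 2) | (s == 2 & d == 0))
    expect_true(all(e[forced_het] == 1L))
    both_a <- auto & s == 0 & d == 0
    expect_true(all(e[both_a] == 0L))
  }
})

test_that("simulated trios contain no Mendelian inconsistencies", {
  sc <- small_cohort(seed = 22)
  fo <- sc$founders; tr <- sc$trios
  ped <- tr$pedigree
  fg <- fo$genotypes$calls
  for (i in seq_len(nrow(tr$embryos$calls))) {
    sex <- ped$sex[match(rownames(tr$embryos$calls)[i], ped$individual_id)]
    fl <- find_mendelian_inconsistencies(
      tr$embryos$calls[i, ],
      fg[match(tr$sires[i], rownames(fg)), ],
      fg[match(tr$dams[i], rownames(fg)), ],
      fo$loci, sex)
    expect_equal(sum(fl), 0)
  }
})

test_that("male embryos carry no heterozygous X before degradation", {
  sc <- small_cohort(seed = 23, n_trios = 12, n_founders = 30)
  tr <- sc$trios
  ped <- tr$pedigree
  x <- is_x_locus(tr$embryos)
  for (i in seq_len(nrow(tr$embryos$calls))) {
    sex <- ped$sex[match(rownames(tr$embryos$calls)[i], ped$individual_id)]
    if (sex == "MALE")
      expect_equal(sum(tr$embryos$calls[i, x] == 1L), 0)
  }
})

test_that("marker effects are reproducible and the index sums traits", {
  loci <- tiny_loci(50)
  e1 <- assign_marker_effects(loci, n_traits = 3, effect_sd = 1,
                              index_weights = c(1, 1, 1), seed = 24)
  e2 <- assign_marker_effects(loci, n_traits = 3, effect_sd = 1,
                              index_weights = c(1, 1, 1), seed = 24)
  expect_identical(e1$effects, e2$effects)

  e0 <- assign_marker_effects(loci, n_traits = 2, effect_sd = 0, seed = 25)
  set.seed(26)
  gm <- genotype_matrix(matrix(sample(0:2, 500, TRUE), 10), loci)
  expect_true(all(compute_dgv(gm, e0) == 0))
})

test_that("quality scores separate poorly by design", {
  sc <- small_cohort(seed = 27, n_loci = 2000, n_trios = 25, n_founders = 52)
  truth <- sc$trios$embryos
  prof <- calibrate_wga_profile(mean(truth$calls == 1L))
  inj <- inject_wga_errors(truth, prof, seed = 28)
  scored <- simulate_quality_scores(inj$degraded, inj$mask, seed = 29)
  called <- !is.na(scored$calls)
  expect_true(all(!is.na(scored$quality[called])))
  expect_true(all(is.na(scored$quality[!called])))
  is_err <- !(inj$mask[called] %in% c("correct", "no_call"))
  sw <- quality_threshold_curve(scored$quality[called], is_err)
  ok <- !is.na(sw$curve$error_removal)
  expect_false(any(sw$curve$error_removal[ok] > 0.9 &
                     sw$curve$correct_retention[ok] > 0.9))

  # identical shape parameters: the score is uninformative (AUC ~ 0.5)
  scored2 <- simulate_quality_scores(inj$degraded, inj$mask,
                                     a_correct = 3, b_correct = 2,
                                     a_error = 3, b_error = 2, seed = 30)
  q2 <- scored2$quality[called]
  qe <- head(q2[is_err], 2000); qc <- head(q2[!is_err], 2000)
  auc <- mean(outer(qe, qc, `<`))  # P(error scores below a correct call)
  expect_lt(abs(auc - 0.5), 0.05)
})
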