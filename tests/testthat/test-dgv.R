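# Direct genomic values, the selection index, and merit concordance.

test_that("single-locus DGV equals the dosage", {
  loci <- tiny_loci(1)
  gm <- genotype_matrix(matrix(c(0L, 1L, 2L), 3, 1), loci)
  eff <- structure(list(effects = matrix(1, 1, 1,
                                         dimnames = list("L001", "t")),
                        trait_names = "t", index_weights = 1,
                        index_scale = 1, index_offset = 0),
                   class = "marker_effect_set")
  expect_equal(unname(compute_dgv(gm, eff)[, 1]), c(0, 1, 2))
})

test_that("DGV matches an explicit per-sample dot product", {
  loci <- tiny_loci(300)
  set.seed(61)
  gm <- genotype_matrix(matrix(sample(0:2, 50 * 300, TRUE), 50), loci)
  eff <- assign_marker_effects(loci, n_traits = 2, effect_sd = 0.5,
                               seed = 62)
  dgv <- compute_dgv(gm, eff)
  for (i in c(1, 17, 50)) for (t in 1:2) {
    manual <- sum(gm$calls[i, ] * eff$effects[, t])
    expect_equal(unname(dgv[i, t]), manual)
  }
  # linearity: DGV of an averaged genotype = average of DGVs
  gavg <- colMeans(gm$calls[1:2, ])
  expect_equal(as.vector(gavg %*% eff$effects),
               unname(colMeans(dgv[1:2, ])))
})

test_that("missing calls are refused", {
  loci <- tiny_loci(3)
  gm <- genotype_matrix(matrix(c(0L, NA, 2L), 1, 3), loci)
  eff <- assign_marker_effects(loci, n_traits = 1, seed = 63)
  expect_error(compute_dgv(gm, eff), "impute")
})

test_that("index is affine-equivariant and permutation-consistent", {
  loci <- tiny_loci(200)
  set.seed(64)
  gm <- genotype_matrix(matrix(sample(0:2, 30 * 200, TRUE), 30), loci)
  eff <- assign_marker_effects(loci, n_traits = 3,
                               index_weights = c(1, 1, 1),
                               index_scale = 100, index_offset = 1000,
                               seed = 65)
  dgv <- compute_dgv(gm, eff)
  idx <- compute_index(dgv, eff)

  eff2 <- eff; eff2$index_scale <- 200
  idx2 <- compute_index(dgv, eff2)
  expect_equal(sd(idx2), 2 * sd(idx))
  expect_equal(order(idx2), order(idx))

  perm <- sample(30)
  idx_p <- compute_index(dgv[perm, ], eff)
  expect_equal(unname(idx_p), unname(idx[perm]))

  # one trait, unit weight/scale, zero offset: z-scored DGV
  eff1 <- eff; eff1$index_weights <- c(1, 0, 0)
  eff1$index_scale <- 1; eff1$index_offset <- 0
  idx1 <- compute_index(dgv, eff1)
  expect_equal(unname(idx1),
               unname((dgv[, 1] - mean(dgv[, 1])) / sd(dgv[, 1])))
})

test_that("merit comparison handles identity and anti-ordering", {
  x <- c(1050, 980, 1210, 1100, 995)
  m <- compare_merit(x, x)
  expect_equal(m$pearson_r, 1)
  expect_equal(m$mean_abs_divergence, 0)
  expect_equal(m$spearman_rho, 1)
  expect_equal(m$top_k_overlap, 1)

  m2 <- compare_merit(x, 2200 - x)
  expect_equal(m2$spearman_rho, -1)
  expect_error(compare_merit(rep(1, 5), x), "variance")
})

test_that("uncorrected degradation erodes merit concordance monotonically", {
  sc <- small_cohort(seed = 71, n_loci = 1500, n_trios = 20, n_founders = 42)
  truth <- sc$trios$embryos
  eff <- assign_marker_effects(truth$loci, n_traits = 2, effect_sd = 1,
                               index_weights = c(1, 1), seed = 72)
  idx_true <- compute_index(compute_dgv(truth, eff), eff)
  r_at <- function(ado) {
    inj <- inject_wga_errors(truth, wga_error_model(ado_rate = ado,
                                                    hetgain_rate = ado / 4),
                             seed = 73)
    idx <- compute_index(compute_dgv(inj$degraded, eff), eff)
    compare_merit(idx, idx_true)$pearson_r
  }
  rs <- vapply(c(0, 0.3, 0.7), r_at, 0)
  expect_equal(rs[1], 1)
  expect_true(rs[2] < rs[1] && rs[3] < rs[2])
})

test_that("marker-effect TSV round-trips", {
  td <- withr::local_tempdir()
  loci <- tiny_loci(20)
  eff <- assign_marker_effects(loci, n_traits = 2, effect_sd = 1,
                               index_weights = c(2, 1), index_scale = 50,
                               index_offset = 900, seed = 66)
  p <- file.path(td, "eff.tsv")
  write_marker_effects(eff, p)
  back <- read_marker_effects(p, loci)
  expect_equal(back$effects, eff$effects, tolerance = 1e-6)
  expect_equal(back$index_weights, eff$index_weights)
  expect_equal(back$index_scale, 50)
  expect_equal(back$index_offset, 900)
})
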