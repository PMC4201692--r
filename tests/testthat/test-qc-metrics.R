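# Error taxonomy, replicate concordance and the statistical checks.

test_that("classify_call maps the error taxonomy totally", {
  expect_equal(classify_call(1L, 0L), "allele_dropout")
  expect_equal(classify_call(1L, 2L), "allele_dropout")
  expect_equal(classify_call(0L, 1L), "het_gain")
  expect_equal(classify_call(0L, 2L), "hom_reversal")
  expect_equal(classify_call(2L, 0L), "hom_reversal")
  expect_equal(classify_call(1L, 1L), "correct")
  expect_equal(classify_call(0L, NA), "no_call")
  expect_error(classify_call(NA, 1L), "reference")
})

test_that("tally identities hold and identity input gives perfect rates", {
  ref <- tiny_gm(rbind(c(0, 1, 2, 1, 0, NA)))
  t <- error_tally(ref, ref)
  expect_equal(t$error_rate, 0)
  expect_equal(t$call_rate, 1)
  expect_equal(t$correct_prop, 1)
  expect_equal(t$n_ref_called, 5)   # reference no-call excluded

  obs <- tiny_gm(rbind(c(0, 0, 1, NA, 2, 1)))
  t2 <- error_tally(ref, obs)
  expect_equal(t2$n_called, t2$n_correct + t2$n_ado + t2$n_hetgain +
                 t2$n_homrev)
  expect_equal(t2$n_ref_called, t2$n_called + t2$n_nocall_vs_ref)
  expect_equal(t2$n_ado, 1)      # HET -> HOM_A
  expect_equal(t2$n_hetgain, 1)  # HOM_B -> HET
  expect_equal(t2$n_homrev, 1)   # HOM_A -> HOM_B
})

test_that("tally agrees exactly with the injection mask", {
  sc <- small_cohort()
  truth <- sc$trios$embryos
  model <- wga_error_model(miss_rate = 0.1, ado_rate = 0.3,
                           hetgain_rate = 0.05, reversal_rate = 0.01)
  inj <- inject_wga_errors(truth, model, seed = 5)
  for (i in c(1, 5)) {
    t <- error_tally(truth, inj$degraded, i)
    expect_equal(t$n_ado, sum(inj$mask[i, ] == "allele_dropout"))
    expect_equal(t$n_hetgain, sum(inj$mask[i, ] == "het_gain"))
    expect_equal(t$n_homrev, sum(inj$mask[i, ] == "hom_reversal"))
    expect_equal(t$n_nocall_vs_ref, sum(inj$mask[i, ] == "no_call"))
  }
})

test_that("uniform random calls approach the 2/3 error floor", {
  set.seed(21)
  L <- 120000
  loci <- data.frame(locus_id = sprintf("s%06d", 1:L), chromosome = "1",
                     position_bp = 1:L)
  ref <- genotype_matrix(matrix(sample(0:2, L, TRUE), 1), loci, "ref")
  obs <- genotype_matrix(matrix(sample(0:2, L, TRUE), 1), loci, "obs")
  t <- error_tally(ref, obs)
  # binomial 99.9% interval around 2/3
  expect_lt(abs(t$error_rate - 2 / 3), 3.3 * sqrt(2 / 9 / L))
})

test_that("replicate concordance fractions are ordered and match forced cases", {
  full <- tiny_gm(rbind(c(0, 1, 2, 1)))
  none <- tiny_gm(rbind(rep(NA_integer_, 4)))
  cs <- replicate_concordance(list(full, full, full))
  expect_equal(c(cs$f_all, cs$f_atleast2, cs$f_any), c(1, 1, 1))
  cs2 <- replicate_concordance(list(full, none, none))
  expect_equal(c(cs2$f_all, cs2$f_atleast2, cs2$f_any), c(0, 0, 1))

  set.seed(31)
  reps <- lapply(1:3, function(i) {
    g <- sample(0:2, 2000, TRUE)
    g[runif(2000) < 0.35] <- NA
    genotype_matrix(matrix(g, 1),
                    data.frame(locus_id = sprintf("s%04d", 1:2000),
                               chromosome = "1", position_bp = 1:2000))
  })
  cs3 <- replicate_concordance(reps)
  expect_true(cs3$f_all <= cs3$f_atleast2 && cs3$f_atleast2 <= cs3$f_any)
  # independent missingness: f_all ~ 0.65^3 within a binomial interval
  expect_lt(abs(cs3$f_all - 0.65^3), 4 * sqrt(0.65^3 * (1 - 0.65^3) / 2000))
})

test_that("binomial concordance expectations match direct arithmetic", {
  e <- expected_binomial_concordance(0.9, 3, 1000)
  expect_equal(e$all, 729)
  expect_equal(e$atleast2, 972)
  expect_equal(e$any, 999)
  e1 <- expected_binomial_concordance(1, 3, 500)
  expect_equal(unlist(e1), c(all = 500, atleast2 = 500, any = 500))
  e0 <- expected_binomial_concordance(0, 3, 500)
  expect_equal(unlist(e0), c(all = 0, atleast2 = 0, any = 0))
})

test_that("locus-effect test returns P = 1 under exact agreement", {
  r <- locus_effect_test(c(100, 200, 300), c(100, 200, 300), 1000)
  expect_equal(r$p_value, 1)
  expect_equal(r$mean_diff, 0)
  expect_error(locus_effect_test(1, 1, 10), "2 paired")
})

test_that("locus-effect test is calibrated under the null and detects dispersion", {
  # under locus-homogeneous missingness the paired t-test on
  # observed-vs-expected all-replicate coverage should be null
  sim_p <- function(dispersion, seed) {
    set.seed(seed)
    loci <- data.frame(locus_id = sprintf("s%04d", 1:1500),
                       chromosome = "1", position_bp = 1:1500)
    obs <- c(); expc <- c()
    for (m in 1:4) {            # four "methods"
      p <- 0.7 + 0.05 * m
      model <- wga_error_model(miss_rate = 1 - p,
                               locus_dispersion = dispersion)
      truth <- genotype_matrix(matrix(sample(0:2, 1500, TRUE), 1), loci)
      reps <- lapply(1:3, function(r)
        inject_wga_errors(truth, model, seed = seed * 100 + m * 10 + r,
                          locus_seed = seed * 100 + m * 10))
      counts <- Reduce(`+`, lapply(reps, function(x)
        !is.na(x$degraded$calls[1, ])))
      p_hat <- mean(vapply(reps, function(x)
        mean(!is.na(x$degraded$calls[1, ])), 0))
      obs <- c(obs, sum(counts == 3))
      expc <- c(expc, expected_binomial_concordance(p_hat, 3, 1500)$all)
    }
    locus_effect_test(obs, expc, 1500)$p_value
  }
  null_p <- vapply(1:300, function(s) sim_p(0, s), 0)
  # nominal 5% type-I within Monte-Carlo slack for 300 replicates
  expect_gt(mean(null_p < 0.05), 0.02)
  expect_lt(mean(null_p < 0.05), 0.09)
  disp_p <- vapply(1:20, function(s) sim_p(0.3, s + 500), 0)
  expect_gt(mean(disp_p < 0.05), 0.8)   # strong power under dispersion
})

test_that("call-rate / error-rate correlation handles colinear points", {
  r <- callrate_error_correlation(c(1, 0.5, 0), c(0, 0.5, 1))
  expect_equal(r$r, -1)
  expect_error(callrate_error_correlation(c(1, 1), c(0, 1)), "3 points")
  expect_error(callrate_error_correlation(c(1, 1, 1), c(0, 0.5, 1)),
               "variance")
})

test_that("quality threshold sweep behaves at the separable and identical limits", {
  q <- c(rep(0.05, 50), rep(0.95, 50))
  err <- c(rep(TRUE, 50), rep(FALSE, 50))
  sw <- quality_threshold_curve(q, err, thresholds = c(0, 0.5, 1))
  row <- sw$curve[sw$curve$threshold == 0.5, ]
  expect_equal(row$error_removal, 1)
  expect_equal(row$correct_retention, 1)

  set.seed(41)
  q2 <- runif(4000)
  err2 <- rep(c(TRUE, FALSE), 2000)
  sw2 <- quality_threshold_curve(q2, err2)
  expect_true(all(abs(sw2$curve$error_removal -
                        (1 - sw2$curve$correct_retention)) < 0.06))
  expect_true(all(diff(sw2$curve$error_removal) >= 0))
  expect_true(all(diff(sw2$curve$correct_retention) <= 0))
})
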