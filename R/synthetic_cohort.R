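# Synthetic BovineSNP50-style cohorts.
#
# The generator reproduces the statistical structure the downstream
# analyses rely on -- not bovine demography.  Founder haplotypes are
# first-order Markov mosaics copied from a small pool of ancestral
# haplotypes, which creates both short-range LD and the long shared
# haplotype segments that family/population imputation exploits (dairy
# cattle have a small effective population, so real haplotypes are
# exactly such mosaics).  Trios get Poisson-count crossovers on a
# uniform genetic map, and the X chromosome is hemizygous in males
# (arrays code a single X allele as a homozygous call).

#' Evaluate and restore the RNG state around a seeded computation
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic fan-out of one user seed into per-stage seeds, so each
# pipeline stage is reproducible in isolation.  Kept below 2^31.
stage_seed <- function(seed, stage) {
  (as.integer(seed) %% 1000003L) * 1009L + match(stage, c(
    "founders", "trios", "effects", "inject", "quality", "replicates",
    "misc")) * 7919L
}

#' Cohort configuration
#'
#' Defaults describe the desk-scale study design used throughout: a
#' ~5,000-locus panel over 29 autosomes plus X (about 1/10 of a 50K
#' chip), 100 founders forming 50 sire-dam-embryo trios, allele-B
#' frequencies uniform on (0.05, 0.5), strong adjacent-locus LD
#' (`ld_rho` 0.9) and a uniform 1 cM/Mb genetic map.
#'
#' @param n_loci Total number of loci on the panel.
#' @param n_autosomes Number of autosomes (cattle: 29).
#' @param x_fraction Fraction of loci on the X chromosome.
#' @param n_founders Number of founders (half male, half female).
#' @param n_trios Number of sire-dam-embryo trios.
#' @param maf_low,maf_high Range of the uniform allele-B frequency draw.
#' @param ld_rho Adjacent-locus haplotype correlation within the
#'   ancestral haplotypes (latent first-order autoregression); 0 gives
#'   linkage equilibrium.
#' @param n_ancestral Size of the ancestral haplotype pool the
#'   founders are mosaics of.
#' @param copy_persistence Per-locus probability that a founder
#'   haplotype keeps copying its current ancestral template; 0.98
#'   gives shared segments of ~50 loci, emulating the long
#'   identical-by-descent segments of a small effective population.
#' @param recomb_cM_per_Mb Uniform genetic map density.
#' @param chrom_length_mb Physical length of each chromosome, Mb.
#' @param seed Integer seed; mandatory.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_loci = 5000, n_autosomes = 29, x_fraction = 0.03,
                          n_founders = 100, n_trios = 50,
                          maf_low = 0.05, maf_high = 0.5, ld_rho = 0.9,
                          n_ancestral = 20, copy_persistence = 0.98,
                          recomb_cM_per_Mb = 1.0,
                          chrom_length_mb = 100, seed) {
  stopifnot(n_loci >= n_autosomes + 1, n_autosomes >= 1,
            x_fraction > 0, x_fraction < 1,
            n_founders >= 2, n_trios >= 1,
            maf_low > 0, maf_low <= maf_high, maf_high <= 0.5,
            ld_rho >= 0, ld_rho < 1, n_ancestral >= 2,
            copy_persistence > 0, copy_persistence <= 1,
            recomb_cM_per_Mb > 0, chrom_length_mb > 0)
  if (missing(seed)) stop("`seed` is mandatory in a cohort config")
  if (n_trios > n_founders %/% 2)
    stop("need at least `n_trios` founders of each sex: increase n_founders")
  structure(list(n_loci = as.integer(n_loci),
                 n_autosomes = as.integer(n_autosomes),
                 x_fraction = x_fraction,
                 n_founders = as.integer(n_founders),
                 n_trios = as.integer(n_trios),
                 maf_low = maf_low, maf_high = maf_high, ld_rho = ld_rho,
                 n_ancestral = as.integer(n_ancestral),
                 copy_persistence = copy_persistence,
                 recomb_cM_per_Mb = recomb_cM_per_Mb,
                 chrom_length_mb = chrom_length_mb,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Panel layout: X gets x_fraction of loci, the rest split as evenly as
# possible over the autosomes; positions evenly spaced per chromosome.
panel_loci <- function(config) {
  n_x <- max(1L, round(config$x_fraction * config$n_loci))
  n_auto <- config$n_loci - n_x
  per_chr <- diff(round(seq(0, n_auto, length.out = config$n_autosomes + 1)))
  chrom <- c(rep(as.character(seq_len(config$n_autosomes)), per_chr),
             rep("X", n_x))
  counts <- c(per_chr, n_x)
  pos <- unlist(lapply(counts, function(k) {
    round(seq(1, config$chrom_length_mb * 1e6, length.out = k + 2)[2:(k + 1)])
  }))
  data.frame(locus_id = sprintf("snp%05d", seq_len(config$n_loci)),
             chromosome = chrom, position_bp = as.integer(pos),
             allele_a = "A", allele_b = "B",
             cM = pos / 1e6 * config$recomb_cM_per_Mb,
             stringsAsFactors = FALSE)
}

# Ancestral pool: latent AR(1) Gaussian per chromosome thresholded at
# the allele frequency, so marginals are exactly the Uniform-drawn
# freqs and adjacent loci correlate with latent coefficient ld_rho.
sample_ancestral_pool <- function(n_ancestral, loci, freqs, ld_rho) {
  h <- matrix(0L, n_ancestral, nrow(loci))
  for (chr in unique(loci$chromosome)) {
    j <- which(loci$chromosome == chr)
    m <- length(j)
    u <- matrix(stats::rnorm(n_ancestral * m), n_ancestral, m)
    if (ld_rho > 0 && m > 1) {
      s <- sqrt(1 - ld_rho^2)
      for (k in 2:m) u[, k] <- ld_rho * u[, k - 1] + s * u[, k]
    }
    h[, j] <- (stats::pnorm(u) < rep(freqs[j], each = n_ancestral)) + 0L
  }
  h
}

# One haplotype panel: each haplotype walks along every chromosome
# copying an ancestral template, keeping the current template with
# probability copy_persistence per locus and re-drawing it uniformly
# otherwise.  ld_rho = 0 bypasses the pool (exact linkage
# equilibrium).
sample_haplotypes <- function(n_hap, loci, freqs, ld_rho, persistence,
                              pool) {
  L <- nrow(loci)
  if (ld_rho == 0)
    return(matrix(stats::rbinom(n_hap * L, 1L, rep(freqs, each = n_hap)),
                  n_hap, L))
  K <- nrow(pool)
  h <- matrix(0L, n_hap, L)
  for (chr in unique(loci$chromosome)) {
    j <- which(loci$chromosome == chr)
    m <- length(j)
    # template index chain, vectorised over haplotypes
    tmpl <- matrix(0L, n_hap, m)
    tmpl[, 1] <- sample.int(K, n_hap, replace = TRUE)
    if (m > 1) {
      switch_ <- matrix(stats::runif(n_hap * (m - 1)) >= persistence,
                        n_hap, m - 1)
      fresh <- matrix(sample.int(K, n_hap * (m - 1), replace = TRUE),
                      n_hap, m - 1)
      for (k in 2:m)
        tmpl[, k] <- ifelse(switch_[, k - 1], fresh[, k - 1], tmpl[, k - 1])
    }
    h[, j] <- matrix(pool[cbind(as.vector(tmpl), rep(j, each = n_hap))],
                     n_hap, m)
  }
  h
}

#' Simulate founder genotypes with LD
#'
#' Draws per-locus allele-B frequencies once from
#' `Uniform(maf_low, maf_high)`, builds a pool of `n_ancestral`
#' ancestral haplotypes with adjacent-locus correlation `ld_rho`
#' (latent Gaussian autoregression, so marginal frequencies are
#' preserved exactly), then generates each founder haplotype as a
#' first-order Markov mosaic of the pool: at every locus the
#' haplotype keeps copying its current ancestral template with
#' probability `copy_persistence` and re-draws a template otherwise.
#' `ld_rho` 0 gives exact linkage equilibrium.  Founders alternate
#' FEMALE/MALE; males carry a single X haplotype whose allele is
#' coded as a homozygous call.
#'
#' @param config A [cohort_config()].
#' @return A list of class `founder_set`: `genotypes` (a
#'   [genotype_matrix()]), `haplotypes` (list of two 0/1 matrices,
#'   paternal-slot and maternal-slot), `pedigree`, `freqs` (allele-B
#'   frequencies), `loci`, `config`.
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  loci <- panel_loci(config)
  with_seed(stage_seed(config$seed, "founders"), {
    freqs <- stats::runif(config$n_loci, config$maf_low, config$maf_high)
    n <- config$n_founders
    pool <- sample_ancestral_pool(config$n_ancestral, loci, freqs,
                                  config$ld_rho)
    h1 <- sample_haplotypes(n, loci, freqs, config$ld_rho,
                            config$copy_persistence, pool)
    h2 <- sample_haplotypes(n, loci, freqs, config$ld_rho,
                            config$copy_persistence, pool)
    sex <- rep(c("FEMALE", "MALE"), length.out = n)
    xj <- which(loci$chromosome == "X")
    # males are hemizygous on X: one haplotype, duplicated into the
    # second slot so the coded genotype is the homozygote of the allele
    h2[sex == "MALE", xj] <- h1[sex == "MALE", xj]
    ids <- sprintf("F%03d", seq_len(n))
    rownames(h1) <- rownames(h2) <- ids
    gm <- genotype_matrix(h1 + h2, loci, sample_ids = ids)
    ped <- pedigree_table(ids, NA, NA, sex)
    structure(list(genotypes = gm, haplotypes = list(h1 = h1, h2 = h2),
                   pedigree = ped, freqs = freqs, loci = loci,
                   config = config),
              class = "founder_set")
  })
}

# A recombinant gamete from one parent's two haplotypes on one
# chromosome: crossover count ~ Poisson(genetic length in Morgans),
# breakpoints uniform in genetic distance.
recombine_chromosome <- function(hap_a, hap_b, cm) {
  len_m <- (max(cm) - min(cm)) / 100
  n_x <- stats::rpois(1, len_m)
  start <- stats::rbinom(1, 1, 0.5)
  if (n_x == 0) {
    phase <- rep(start, length(cm))
  } else {
    br <- sort(stats::runif(n_x, min(cm), max(cm)))
    phase <- (start + findInterval(cm, br)) %% 2
  }
  ifelse(phase == 0, hap_a, hap_b)
}

#' Simulate sire-dam-embryo trios
#'
#' Pairs the male and female founders into `n_trios` couples and draws
#' one embryo per couple.  Each embryo receives one recombinant gamete
#' per parent (Poisson crossover counts on the genetic map); sex is
#' Bernoulli(0.5).  Male embryos inherit X only from the dam and are
#' coded homozygous there; female embryos receive the sire's single X
#' haplotype unrecombined.  Trios are Mendelian-consistent by
#' construction.
#'
#' @param founders A `founder_set` from [simulate_founders()].
#' @param config The same [cohort_config()].
#' @return A list of class `trio_set`: `embryos` (genotype matrix),
#'   `haplotypes` (true phased embryo haplotypes: `pat`, `mat`),
#'   `pedigree` (founders plus embryos), `sires`, `dams` (id vectors),
#'   plus the founder set.
#' @export
simulate_trios <- function(founders, config = founders$config) {
  stopifnot(inherits(founders, "founder_set"))
  ped <- founders$pedigree
  males <- ped$individual_id[ped$sex == "MALE"]
  females <- ped$individual_id[ped$sex == "FEMALE"]
  if (length(males) < config$n_trios || length(females) < config$n_trios)
    stop("insufficient founders of one sex for the requested trios")
  sires <- males[seq_len(config$n_trios)]
  dams <- females[seq_len(config$n_trios)]
  loci <- founders$loci
  xj <- loci$chromosome == "X"
  chrs <- split(seq_len(nrow(loci)), loci$chromosome)

  with_seed(stage_seed(config$seed, "trios"), {
    n <- config$n_trios
    pat <- matrix(0L, n, nrow(loci))
    mat <- matrix(0L, n, nrow(loci))
    sex <- ifelse(stats::runif(n) < 0.5, "MALE", "FEMALE")
    for (i in seq_len(n)) {
      s <- match(sires[i], ped$individual_id)
      d <- match(dams[i], ped$individual_id)
      for (chr in names(chrs)) {
        j <- chrs[[chr]]
        cm <- loci$cM[j]
        mat[i, j] <- recombine_chromosome(founders$haplotypes$h1[d, j],
                                          founders$haplotypes$h2[d, j], cm)
        if (chr == "X") {
          if (sex[i] == "MALE") {
            # son: X from dam only; coded as homozygote of that allele
            pat[i, j] <- mat[i, j]
          } else {
            # daughter: sire's single X haplotype, unrecombined
            pat[i, j] <- founders$haplotypes$h1[s, j]
          }
        } else {
          pat[i, j] <- recombine_chromosome(founders$haplotypes$h1[s, j],
                                            founders$haplotypes$h2[s, j], cm)
        }
      }
    }
    ids <- sprintf("E%03d", seq_len(n))
    rownames(pat) <- rownames(mat) <- ids
    embryos <- genotype_matrix(pat + mat, loci, sample_ids = ids)
    ped_all <- pedigree_table(c(ped$individual_id, ids),
                              c(ped$sire_id, sires),
                              c(ped$dam_id, dams),
                              c(ped$sex, sex))
    structure(list(embryos = embryos,
                   haplotypes = list(pat = pat, mat = mat),
                   pedigree = ped_all, sires = sires, dams = dams,
                   founders = founders, config = config),
              class = "trio_set")
  })
}

#' Simulate additive marker effects and an index definition
#'
#' Effects play the role of an external genomic-evaluation oracle: one
#' additive effect per copy of allele B per locus and trait, drawn
#' Normal(0, `effect_sd`^2).  X-linked effects are included with dosage
#' as coded (males 0/2).
#'
#' @param loci Locus map data frame.
#' @param n_traits Number of traits.
#' @param effect_sd Standard deviation of the per-locus effects.
#' @param index_weights Per-trait economic weights (recycled).
#' @param index_scale,index_offset Affine scale of the published index.
#' @param seed Integer seed.
#' @return A list of class `marker_effect_set`.
#' @export
assign_marker_effects <- function(loci, n_traits = 3, effect_sd = 1,
                                  index_weights = 1, index_scale = 100,
                                  index_offset = 1000, seed) {
  stopifnot(n_traits >= 1, effect_sd >= 0)
  traits <- sprintf("trait%d", seq_len(n_traits))
  w <- rep_len(index_weights, n_traits)
  with_seed(seed, {
    eff <- matrix(stats::rnorm(nrow(loci) * n_traits, 0, effect_sd),
                  nrow(loci), n_traits,
                  dimnames = list(loci$locus_id, traits))
    structure(list(effects = eff, trait_names = traits, index_weights = w,
                   index_scale = index_scale, index_offset = index_offset),
              class = "marker_effect_set")
  })
}

#' Attach simulated per-call quality scores
#'
#' Correct calls draw their score from Beta(`a_correct`, `b_correct`),
#' erroneous calls from Beta(`a_error`, `b_error`).  The defaults (8,2)
#' and (3,2) overlap over the whole unit interval, reproducing the
#' situation where no score threshold separates errors from correct
#' calls.
#'
#' @param genotypes A [genotype_matrix()] (typically WGA-degraded).
#' @param error_mask Character matrix of per-cell categories as produced
#'   by [inject_wga_errors()]; any category other than "correct" and
#'   "no_call" counts as erroneous.
#' @param a_correct,b_correct,a_error,b_error Beta shape parameters.
#' @param seed Integer seed.
#' @return The genotype matrix with `quality` filled on all called
#'   cells (no-calls keep `NA`).
#' @export
simulate_quality_scores <- function(genotypes, error_mask,
                                    a_correct = 8, b_correct = 2,
                                    a_error = 3, b_error = 2, seed) {
  stopifnot(identical(dim(error_mask), dim(genotypes$calls)))
  with_seed(seed, {
    q <- matrix(NA_real_, nrow(genotypes$calls), ncol(genotypes$calls))
    called <- !is.na(genotypes$calls)
    err <- called & !(error_mask %in% c("correct", "no_call"))
    ok <- called & !err
    q[ok] <- stats::rbeta(sum(ok), a_correct, b_correct)
    q[err] <- stats::rbeta(sum(err), a_error, b_error)
    genotype_matrix(genotypes$calls, genotypes$loci,
                    rownames(genotypes$calls), quality = q)
  })
}
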