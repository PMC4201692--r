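# Mendelian-inconsistency correction and combined family/population
# imputation.
#
# The repair pipeline for a degraded embryo with genotyped parents:
#   1. flag calls impossible under Mendelian transmission and blank them;
#   2. fill what the parents force outright (family rules);
#   3. trace the transmitted parental haplotypes along each chromosome
#      with a small HMM over the four (sire hap, dam hap) combinations,
#      using the phased parent haplotypes from the library; the traced
#      path fills every remaining gap and overrides called genotypes
#      that the haplotypes confidently contradict (this is how
#      Mendelian-consistent errors -- e.g. drop-outs under HET x HET
#      parents -- get caught);
#   4. samples without genotyped parents fall back to library window
#      matching.
# The X is handled sex-aware: a male embryo carries only a maternal X,
# coded homozygous.

# Which alleles can a parent with coded genotype g transmit?
can_transmit_a <- function(g) is.na(g) | g <= 1L   # allele 0 (A)
can_transmit_b <- function(g) is.na(g) | g >= 1L   # allele 1 (B)

#' Find Mendelian inconsistencies in a trio
#'
#' A locus is flagged iff the embryo's call is impossible given the
#' called parent genotypes under Mendelian transmission.  Unknown or
#' uncalled parents impose no constraint.  On the X, a male embryo must
#' be homozygous for an allele its dam carries; a female embryo treats
#' the sire's coded (homozygous) X genotype as his single allele.
#'
#' @param embryo,sire,dam Dosage vectors over the same loci (sire/dam
#'   may be `NULL` for an unknown parent).
#' @param loci Locus map data frame.
#' @param embryo_sex "MALE", "FEMALE" or "UNKNOWN" (unknown sex checks
#'   the X only against constraints shared by both sexes).
#' @return Logical vector: flagged loci.
#' @export
find_mendelian_inconsistencies <- function(embryo, sire = NULL, dam = NULL,
                                           loci, embryo_sex = "UNKNOWN") {
  L <- length(embryo)
  if (is.null(sire)) sire <- rep(NA_integer_, L)
  if (is.null(dam)) dam <- rep(NA_integer_, L)
  stopifnot(length(sire) == L, length(dam) == L, nrow(loci) == L)
  x <- loci$chromosome == "X"

  sa <- can_transmit_a(sire); sb <- can_transmit_b(sire)
  da <- can_transmit_a(dam); db <- can_transmit_b(dam)
  possible0 <- sa & da
  possible1 <- (sa & db) | (sb & da)
  possible2 <- sb & db

  flag <- !is.na(embryo) &
    ((embryo == 0L & !possible0) |
     (embryo == 1L & !possible1) |
     (embryo == 2L & !possible2))

  if (any(x)) {
    male_x_flag <- !is.na(embryo[x]) &
      (embryo[x] == 1L |                     # hemizygote cannot be het
       (embryo[x] == 0L & !da[x]) |
       (embryo[x] == 2L & !db[x]))
    if (embryo_sex == "MALE") {
      flag[x] <- male_x_flag
    } else if (embryo_sex == "UNKNOWN") {
      # flag only what is impossible for both a male and a female
      flag[x] <- flag[x] & male_x_flag
    }
  }
  flag
}

#' Blank flagged loci
#'
#' @param embryo Dosage vector.
#' @param flags Logical vector from [find_mendelian_inconsistencies()].
#' @return List `calls` (with flagged loci set to `NA`) and
#'   `n_corrected`.
#' @export
correct_inconsistencies <- function(embryo, flags) {
  embryo[flags] <- NA_integer_
  list(calls = embryo, n_corrected = sum(flags))
}

#' Family-rule imputation
#'
#' Deterministic fills only: a missing embryo genotype is written when
#' both parental contributions are forced (both parents homozygous;
#' on the X of a male embryo, a homozygous dam).  A single homozygous
#' parent fixes one allele, which is recorded as a half-resolved
#' constraint for the downstream haplotype steps.
#'
#' @inheritParams find_mendelian_inconsistencies
#' @return List `calls`, `pat_allele`, `mat_allele` (0/1/NA constraint
#'   vectors), `n_filled`.
#' @export
impute_family <- function(embryo, sire = NULL, dam = NULL, loci,
                          embryo_sex = "UNKNOWN") {
  L <- length(embryo)
  if (is.null(sire)) sire <- rep(NA_integer_, L)
  if (is.null(dam)) dam <- rep(NA_integer_, L)
  x <- loci$chromosome == "X"

  pat <- rep(NA_integer_, L)
  mat <- rep(NA_integer_, L)
  pat[!is.na(sire) & sire == 0L] <- 0L
  pat[!is.na(sire) & sire == 2L] <- 1L
  mat[!is.na(dam) & dam == 0L] <- 0L
  mat[!is.na(dam) & dam == 2L] <- 1L
  if (embryo_sex == "FEMALE") {
    # sire's coded X homozygote is his single allele; het coded sire X
    # (not expected) is left unconstrained
    pat[x & !is.na(sire) & sire == 0L] <- 0L
    pat[x & !is.na(sire) & sire == 2L] <- 1L
  }
  if (embryo_sex == "MALE") pat[x] <- NA_integer_  # no paternal X

  # embryo's own calls also pin down constraints where it is homozygous
  pat[!is.na(embryo) & embryo == 0L] <- 0L
  mat[!is.na(embryo) & embryo == 0L] <- 0L
  pat[!is.na(embryo) & embryo == 2L] <- 1L
  mat[!is.na(embryo) & embryo == 2L] <- 1L

  out <- embryo
  fill <- is.na(out) & !is.na(pat) & !is.na(mat) & !x
  out[fill] <- pat[fill] + mat[fill]
  if (embryo_sex == "MALE") {
    fx <- is.na(out) & x & !is.na(mat)
    out[fx] <- 2L * mat[fx]
    fill <- fill | fx
  } else {
    fx <- is.na(out) & x & !is.na(pat) & !is.na(mat)
    out[fx] <- pat[fx] + mat[fx]
    fill <- fill | fx
  }
  list(calls = out, pat_allele = pat, mat_allele = mat,
       n_filled = sum(fill))
}

# Genotype-given-truth channel used as the HMM emission model.  Either
# a single symmetric error rate, or the drop-out-dominant rates of a
# fitted [wga_error_model()] (a true HET drops to either homozygote
# with ado/2 each; a true HOM gains heterozygosity or, rarely,
# reverses).
channel_matrix <- function(error_rate) {
  if (inherits(error_rate, "wga_error_model")) {
    ado <- error_rate$ado_rate
    hg <- error_rate$hetgain_rate
    rv <- error_rate$reversal_rate
    rbind(c(1 - hg - rv, hg, rv),         # truth 0
          c(ado / 2, 1 - ado, ado / 2),   # truth 1
          c(rv, hg, 1 - hg - rv))         # truth 2
  } else {
    e <- error_rate
    rbind(c(1 - e, 0.8 * e, 0.2 * e),
          c(e / 2, 1 - e, e / 2),
          c(0.2 * e, 0.8 * e, 1 - e))
  }
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Forward-backward over the four (sire hap, dam hap) transmission
# states on one chromosome.  `pred` holds the predicted genotype per
# state (4 x m).  Returns the posterior genotype distribution per
# locus.
transmission_posterior <- function(obs, pred, cm, error_rate,
                                   switch_floor) {
  m <- length(obs)
  E <- channel_matrix(error_rate)
  called <- !is.na(obs)
  em <- matrix(0, 4, m)
  for (s in 1:4)
    em[s, called] <- log(pmax(
      E[cbind(pred[s, called] + 1L, obs[called] + 1L)], 1e-300))

  d <- pmax(diff(cm), 0) / 100
  r <- pmin(0.5 * (1 - exp(-2 * d)) + switch_floor, 0.49)
  same <- log(1 - r); diff_ <- log(r)
  # state order: (s1,d1), (s1,d2), (s2,d1), (s2,d2)
  sire_of <- c(1L, 1L, 2L, 2L); dam_of <- c(1L, 2L, 1L, 2L)
  fwd <- matrix(-Inf, 4, m)
  fwd[, 1] <- log(0.25) + em[, 1]
  if (m > 1) for (t in 2:m) {
    for (s in 1:4) {
      step <- ifelse(sire_of == sire_of[s], same[t - 1], diff_[t - 1]) +
              ifelse(dam_of == dam_of[s], same[t - 1], diff_[t - 1])
      fwd[s, t] <- log_sum_exp(fwd[, t - 1] + step) + em[s, t]
    }
  }
  bwd <- matrix(0, 4, m)
  if (m > 1) for (t in (m - 1):1) {
    for (s in 1:4) {
      step <- ifelse(sire_of == sire_of[s], same[t], diff_[t]) +
              ifelse(dam_of == dam_of[s], same[t], diff_[t])
      bwd[s, t] <- log_sum_exp(step + em[, t + 1] + bwd[, t + 1])
    }
  }
  post <- fwd + bwd
  post <- apply(post, 2, function(col) {
    p <- exp(col - max(col)); p / sum(p)
  })
  if (m == 1) post <- matrix(post, 4, 1)
  gp <- matrix(0, 3, m)
  for (s in 1:4)
    gp[cbind(pred[s, ] + 1L, seq_len(m))] <-
      gp[cbind(pred[s, ] + 1L, seq_len(m))] + post[s, ]
  gp
}

#' Correct and impute one embryo against phased parents
#'
#' Runs the full repair: Mendelian flag-and-blank, family fills, then
#' per-chromosome transmission tracing against the parents' library
#' haplotypes.  Missing loci are filled with the maximum-posterior
#' genotype; a called locus is overridden when the posterior (which
#' already weighs the call itself through the emission model) puts at
#' least `override_posterior` mass on a different genotype.
#'
#' @param embryo Dosage vector of the degraded embryo.
#' @param sire_id,dam_id Library sample ids of the parents (either may
#'   be `NA`; with no genotyped parent the sample is sent to
#'   [impute_population()]).
#' @param library A `haplotype_library` containing the parents.
#' @param loci Locus map (must match the library).
#' @param embryo_sex "MALE", "FEMALE" or "UNKNOWN".
#' @param error_rate Emission model of the tracer: either a single
#'   assumed conditional error rate, or a [wga_error_model()] (e.g.
#'   from [estimate_error_model()]) whose drop-out/drop-in rates shape
#'   the channel.
#' @param switch_floor Baseline per-interval haplotype switch
#'   probability added to the genetic-map recombination fraction;
#'   absorbs residual phase switches in the library.
#' @param override_posterior Posterior mass required before a called
#'   genotype is replaced by the traced one.
#' @return List `calls` (complete dosage vector), `n_mendel`,
#'   `n_family_filled`, `n_overridden`, `n_hmm_filled`.
#' @export
correct_and_impute <- function(embryo, sire_id, dam_id, library, loci,
                               embryo_sex = "UNKNOWN", error_rate = 0.12,
                               switch_floor = 0.002,
                               override_posterior = 0.5) {
  si <- if (!is.na(sire_id)) match(sire_id, library$sample_ids) else NA_integer_
  di <- if (!is.na(dam_id)) match(dam_id, library$sample_ids) else NA_integer_
  sire_g <- if (!is.na(si)) library$h1[si, ] + library$h2[si, ] else NULL
  dam_g <- if (!is.na(di)) library$h1[di, ] + library$h2[di, ] else NULL

  flags <- find_mendelian_inconsistencies(embryo, sire_g, dam_g, loci,
                                          embryo_sex)
  cc <- correct_inconsistencies(embryo, flags)
  fam <- impute_family(cc$calls, sire_g, dam_g, loci, embryo_sex)
  calls <- fam$calls

  if (is.na(si) || is.na(di)) {
    calls <- impute_population(calls, library, loci,
                               pat_allele = fam$pat_allele,
                               mat_allele = fam$mat_allele)
    return(list(calls = calls, n_mendel = cc$n_corrected,
                n_family_filled = fam$n_filled, n_overridden = 0L,
                n_hmm_filled = sum(is.na(fam$calls))))
  }

  sh <- rbind(library$h1[si, ], library$h2[si, ])
  dh <- rbind(library$h1[di, ], library$h2[di, ])
  x <- loci$chromosome == "X"
  n_over <- 0L; n_fill <- 0L
  for (chr_idx in split(seq_along(calls), loci$chromosome)) {
    obs <- calls[chr_idx]
    m <- length(chr_idx)
    male_x <- x[chr_idx[1]] && embryo_sex == "MALE"
    # predicted genotype per transmission state
    pred <- matrix(0L, 4, m)
    k <- 1L
    for (s in 1:2) for (d in 1:2) {
      pred[k, ] <- if (male_x) 2L * dh[d, chr_idx] else
        sh[s, chr_idx] + dh[d, chr_idx]
      k <- k + 1L
    }
    gp <- transmission_posterior(obs, pred, loci$cM[chr_idx],
                                 error_rate, switch_floor)
    map_g <- max.col(t(gp), ties.method = "first") - 1L
    map_p <- gp[cbind(map_g + 1L, seq_along(chr_idx))]
    fill <- is.na(obs)
    over <- !fill & obs != map_g & map_p >= override_posterior
    obs[fill | over] <- map_g[fill | over]
    calls[chr_idx] <- obs
    n_over <- n_over + sum(over)
    n_fill <- n_fill + sum(fill)
  }
  list(calls = calls, n_mendel = cc$n_corrected,
       n_family_filled = fam$n_filled, n_overridden = n_over,
       n_hmm_filled = n_fill)
}

#' Population window imputation against a haplotype library
#'
#' For samples without genotyped parents: slides windows from longest
#' to shortest along each chromosome, selects the library haplotype
#' pair most compatible with the sample's called genotypes (and any
#' fixed parental-allele constraints) in the window, and fills still-
#' missing loci from that pair.  The final single-locus pass guarantees
#' completion from the library allele frequencies, so the output
#' contains no missing call.
#'
#' @param calls Dosage vector with missing loci.
#' @param library A `haplotype_library`.
#' @param loci Locus map.
#' @param pat_allele,mat_allele Optional 0/1/NA constraint vectors.
#' @return Complete dosage vector.
#' @export
impute_population <- function(calls, library, loci,
                              pat_allele = NULL, mat_allele = NULL) {
  if (!length(library$sample_ids)) stop("empty haplotype library")
  L <- length(calls)
  if (is.null(pat_allele)) pat_allele <- rep(NA_integer_, L)
  if (is.null(mat_allele)) mat_allele <- rep(NA_integer_, L)
  H <- rbind(library$h1, library$h2)
  chrs <- split(seq_len(L), loci$chromosome)
  for (w in library$window_lengths) {
    if (!anyNA(calls)) break
    if (w == 1) break
    for (chr_idx in chrs) {
      m <- length(chr_idx)
      if (m < 2) next
      starts <- unique(c(seq(1, max(1, m - w + 1), by = max(1, w %/% 2)),
                         max(1, m - w + 1)))
      for (s in starts) {
        j <- chr_idx[s:min(m, s + w - 1)]
        if (!anyNA(calls[j])) next
        g <- calls[j]
        hom <- !is.na(g) & g != 1L
        known1 <- ifelse(hom, g / 2L, pat_allele[j])      # hap-1 side
        info1 <- !is.na(known1)
        if (sum(info1) < 2) next
        Hw <- H[, j, drop = FALSE]
        sc1 <- 1 - colMeans(abs(t(Hw[, info1, drop = FALSE]) -
                                  known1[info1]))
        c1 <- which.max(sc1)
        if (sc1[c1] < library$min_match) next
        known2 <- ifelse(hom, g / 2L,
                         ifelse(!is.na(g) & g == 1L, 1L - Hw[c1, ],
                                mat_allele[j]))
        info2 <- !is.na(known2)
        if (sum(info2) < 2) next
        sc2 <- 1 - colMeans(abs(t(Hw[, info2, drop = FALSE]) -
                                  known2[info2]))
        c2 <- which.max(sc2)
        if (sc2[c2] < library$min_match) next
        fill <- is.na(calls[j])
        calls[j][fill] <- Hw[c1, fill] + Hw[c2, fill]
      }
    }
  }
  # guaranteed completion: single-locus fallback from allele
  # frequencies, honouring any fixed parental allele
  left <- which(is.na(calls))
  for (j in left) {
    f <- library$freqs[j]
    a1 <- if (!is.na(pat_allele[j])) pat_allele[j] else as.integer(f >= 0.5)
    a2 <- if (!is.na(mat_allele[j])) mat_allele[j] else as.integer(f >= 0.5)
    calls[j] <- a1 + a2
  }
  calls
}

# Wright's kinship by recursion over the pedigree (memoised); the
# inbreeding coefficient of an individual is the kinship of its
# parents.
kinship_coef <- function(a, b, ped, memo = new.env(parent = emptyenv())) {
  if (is.na(a) || is.na(b)) return(0)
  key <- paste(sort(c(a, b)), collapse = "|")
  if (!is.null(memo[[key]])) return(memo[[key]])
  ia <- match(a, ped$individual_id); ib <- match(b, ped$individual_id)
  if (is.na(ia) || is.na(ib)) return(0)
  # recurse on the younger individual (appears later in the table)
  if (ia < ib) { tmp <- a; a <- b; b <- tmp; tmp <- ia; ia <- ib; ib <- tmp }
  val <- if (a == b) {
    0.5 * (1 + kinship_coef(ped$sire_id[ia], ped$dam_id[ia], ped, memo))
  } else {
    0.5 * (kinship_coef(ped$sire_id[ia], b, ped, memo) +
           kinship_coef(ped$dam_id[ia], b, ped, memo))
  }
  memo[[key]] <- val
  val
}

#' Pedigree inbreeding coefficient
#'
#' @param individual Individual id.
#' @param pedigree A [pedigree_table()] (ancestors must precede
#'   descendants).
#' @return Wright's F (kinship of the parents); 0 for unknown parents.
#' @export
pedigree_inbreeding <- function(individual, pedigree) {
  i <- match(individual, pedigree$individual_id)
  if (is.na(i)) stop("individual not in pedigree")
  kinship_coef(pedigree$sire_id[i], pedigree$dam_id[i], pedigree)
}

#' Imputation quality report
#'
#' @param before,after Genotype matrices (pre- and post-imputation)
#'   over the same samples and loci.
#' @param pedigree A [pedigree_table()] covering the samples.
#' @param freqs Allele-B frequencies (e.g. from the library) for the
#'   expected-heterozygosity baseline.
#' @param truth Optional truth matrix; adds per-sample residual error
#'   rates.
#' @return Data frame, one row per sample: `n_missing_before`,
#'   `final_missing_rate`, `homozygosity_rate`, `genomic_inbreeding`
#'   (1 - observed/expected heterozygosity), `pedigree_inbreeding`,
#'   `inbreeding_divergence`, and `residual_error_rate` when truth is
#'   supplied.
#' @export
imputation_report <- function(before, after, pedigree, freqs,
                              truth = NULL) {
  stopifnot(identical(dim(before$calls), dim(after$calls)))
  exp_het <- mean(2 * freqs * (1 - freqs))
  rows <- lapply(seq_len(nrow(after$calls)), function(i) {
    id <- rownames(after$calls)[i]
    g <- after$calls[i, ]
    obs_het <- mean(g == 1L, na.rm = TRUE)
    fped <- pedigree_inbreeding(id, pedigree)
    fgen <- 1 - obs_het / exp_het
    out <- data.frame(
      sample_id = id,
      n_missing_before = sum(is.na(before$calls[i, ])),
      final_missing_rate = mean(is.na(g)),
      homozygosity_rate = mean(g != 1L, na.rm = TRUE),
      genomic_inbreeding = fgen,
      pedigree_inbreeding = fped,
      inbreeding_divergence = fgen - fped,
      stringsAsFactors = FALSE)
    if (!is.null(truth))
      out$residual_error_rate <- mean(g != truth$calls[i, ], na.rm = TRUE)
    out
  })
  do.call(rbind, rows)
}
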