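# WGA degradation: the error channel an amplified biopsy passes through.
#
# Four per-cell events, mutually exclusive (missingness is drawn first,
# so error rates are conditional on a call being made, matching how
# error rate is reported relative to the number of calls):
#   no_call        any truth  -> NA         prob miss_rate
#   allele_dropout HET        -> HOM_A/HOM_B (1:1)  prob ado_rate
#   het_gain       HOM        -> HET        prob hetgain_rate
#   hom_reversal   HOM        -> opposite HOM  prob reversal_rate
# With locus_dispersion > 0 the per-locus miss rate is Beta-distributed
# around miss_rate, giving the locus-specific call-rate bias that the
# locus-effect test is designed to detect.

MASK_LEVELS <- c("correct", "no_call", "allele_dropout", "het_gain",
                 "hom_reversal")

#' Define a WGA error model
#'
#' @param miss_rate Probability a call is lost (NO_CALL).
#' @param ado_rate Conditional probability that a true heterozygote is
#'   called as a random homozygote (allele drop-out).
#' @param hetgain_rate Conditional probability that a true homozygote is
#'   called heterozygous (allele drop-in).
#' @param reversal_rate Conditional probability that a true homozygote
#'   is called as the opposite homozygote.
#' @param locus_dispersion Nonnegative over-dispersion of the per-locus
#'   miss rate: 0 means every locus shares `miss_rate`; larger values
#'   spread per-locus rates as Beta(m/d, (1-m)/d) with d =
#'   `locus_dispersion`.
#' @param name Optional profile name.
#' @return A list of class `wga_error_model`.
#' @export
wga_error_model <- function(miss_rate = 0, ado_rate = 0, hetgain_rate = 0,
                            reversal_rate = 0, locus_dispersion = 0,
                            name = NULL) {
  rates <- c(miss_rate, ado_rate, hetgain_rate, reversal_rate)
  stopifnot(all(rates >= 0), all(rates <= 1), locus_dispersion >= 0,
            hetgain_rate + reversal_rate <= 1)
  structure(list(miss_rate = miss_rate, ado_rate = ado_rate,
                 hetgain_rate = hetgain_rate, reversal_rate = reversal_rate,
                 locus_dispersion = locus_dispersion, name = name),
            class = "wga_error_model")
}

#' Calibrate an error model to a target conditional error rate
#'
#' Chooses (`ado_rate`, `hetgain_rate`, `reversal_rate`) so that the
#' overall erroneous fraction of *called* genotypes equals
#' `conditional_error` for a cohort whose truth is heterozygous at a
#' fraction `het_fraction` of calls.  `ado_share` fixes how much of the
#' error mass is allele drop-out (the drop-out-dominant signature of
#' the better-performing amplification chemistries); the homozygote
#' share is split 90/10 between het_gain and hom_reversal, reversal
#' being the rare double event.
#'
#' @param het_fraction Expected fraction of called cells whose true
#'   genotype is heterozygous.
#' @param conditional_error Target erroneous fraction of calls.
#' @param ado_share Fraction of errors that are allele drop-outs.
#' @param miss_rate,locus_dispersion Passed through to the model.
#' @param name Profile name.
#' @return A `wga_error_model`.
#' @export
calibrate_wga_profile <- function(het_fraction, conditional_error = 0.124,
                                  ado_share = 0.8, miss_rate = 0.12,
                                  locus_dispersion = 0, name = "calibrated") {
  stopifnot(het_fraction > 0, het_fraction < 1,
            conditional_error >= 0, conditional_error < 1,
            ado_share >= 0, ado_share <= 1)
  ado <- ado_share * conditional_error / het_fraction
  hom_err <- (1 - ado_share) * conditional_error / (1 - het_fraction)
  if (ado > 1 || hom_err > 1)
    stop("target conditional error unreachable with this het_fraction/ado_share")
  wga_error_model(miss_rate = miss_rate, ado_rate = ado,
                  hetgain_rate = 0.9 * hom_err, reversal_rate = 0.1 * hom_err,
                  locus_dispersion = locus_dispersion, name = name)
}

#' Default method profiles
#'
#' Eight profiles spanning the performance range of the amplification
#' systems the study design contrasts: from a clean unamplified-like
#' reference through drop-out-dominant isothermal chemistries down to
#' ligation-based methods whose conditional error approaches the
#' random-genotype floor.  Higher miss rates come with higher error
#' rates (a shared template-loss cause), which is what drives the
#' negative call-rate/error-rate correlation.
#'
#' @param het_fraction Expected heterozygous fraction of the cohort the
#'   profiles will degrade.
#' @return Named list of `wga_error_model` objects.
#' @export
default_wga_profiles <- function(het_fraction = 0.37) {
  specs <- list(
    reference_like  = c(miss = 0.003, err = 0.001, ado = 0.5),
    genomiphi_like  = c(miss = 0.12,  err = 0.124, ado = 0.8),
    qpls_like       = c(miss = 0.30,  err = 0.21,  ado = 0.45),
    replig_like     = c(miss = 0.45,  err = 0.30,  ado = 0.85),
    spia_like       = c(miss = 0.50,  err = 0.45,  ado = 0.6),
    lma_expresslink = c(miss = 0.60,  err = 0.53,  ado = 0.5),
    lma_ligafast    = c(miss = 0.65,  err = 0.58,  ado = 0.5),
    lma_like        = c(miss = 0.70,  err = 0.61,  ado = 0.5))
  out <- lapply(names(specs), function(nm) {
    s <- specs[[nm]]
    calibrate_wga_profile(het_fraction, conditional_error = s[["err"]],
                          ado_share = s[["ado"]], miss_rate = s[["miss"]],
                          name = nm)
  })
  names(out) <- names(specs)
  out
}

#' Inflate an error model's conditional rates
#'
#' Scales the drop-out/drop-in/reversal rates by a common factor
#' (capped at valid probabilities).  Used when an error model serves
#' as an HMM emission channel: treating observed calls as slightly
#' less reliable than their nominal rates compensates for other
#' idealisations (e.g. that library haplotypes are exact).
#'
#' @param model A [wga_error_model()].
#' @param factor Multiplicative inflation of the conditional error
#'   rates.
#' @return A `wga_error_model`.
#' @export
inflate_channel <- function(model, factor = 1.3) {
  stopifnot(inherits(model, "wga_error_model"), factor >= 0)
  m <- model
  m$ado_rate <- min(1, model$ado_rate * factor)
  hg <- model$hetgain_rate * factor
  rv <- model$reversal_rate * factor
  if (hg + rv > 1) { s <- 1 / (hg + rv); hg <- hg * s; rv <- rv * s }
  m$hetgain_rate <- hg
  m$reversal_rate <- rv
  m
}

#' Inject WGA errors into a clean genotype matrix
#'
#' Applies the error channel cell-wise and records what happened to
#' every cell in a category mask.  The truth matrix must be fully
#' called.
#'
#' @param truth A fully-called [genotype_matrix()].
#' @param model A [wga_error_model()].
#' @param seed Integer seed for the per-cell events.
#' @param locus_seed Integer seed for the per-locus miss rates drawn
#'   under `locus_dispersion > 0`.  Locus effects are systematic
#'   (sequence-driven), so technical replicates of the same method
#'   must share `locus_seed` while differing in `seed`; the default
#'   ties it to `seed` for one-off use.
#' @return List with `degraded` (genotype matrix) and `mask` (character
#'   matrix over "correct", "no_call", "allele_dropout", "het_gain",
#'   "hom_reversal").
#' @export
inject_wga_errors <- function(truth, model, seed, locus_seed = seed) {
  stopifnot(inherits(truth, "genotype_matrix"),
            inherits(model, "wga_error_model"))
  if (anyNA(truth$calls))
    stop("truth matrix contains NO_CALL; error injection needs full truth")
  n <- nrow(truth$calls); L <- ncol(truth$calls)
  if (model$locus_dispersion > 0 && model$miss_rate > 0) {
    d <- model$locus_dispersion
    locus_miss <- with_seed(locus_seed,
      stats::rbeta(L, model$miss_rate / d, (1 - model$miss_rate) / d))
  } else {
    locus_miss <- rep(model$miss_rate, L)
  }
  with_seed(seed, {
    u_miss <- matrix(stats::runif(n * L), n, L)
    is_miss <- u_miss < rep(locus_miss, each = n)

    g <- truth$calls
    mask <- matrix("correct", n, L)
    u_err <- matrix(stats::runif(n * L), n, L)
    u_dir <- matrix(stats::runif(n * L), n, L)

    het <- g == 1L & !is_miss
    ado <- het & u_err < model$ado_rate
    hom <- g != 1L & !is_miss
    hg <- hom & u_err < model$hetgain_rate
    hr <- hom & !hg & u_err < model$hetgain_rate + model$reversal_rate

    out <- g
    out[ado] <- ifelse(u_dir[ado] < 0.5, 0L, 2L)
    out[hg] <- 1L
    out[hr] <- 2L - g[hr]
    out[is_miss] <- NA_integer_
    mask[ado] <- "allele_dropout"
    mask[hg] <- "het_gain"
    mask[hr] <- "hom_reversal"
    mask[is_miss] <- "no_call"
    dimnames(mask) <- dimnames(truth$calls)
    list(degraded = genotype_matrix(out, truth$loci, rownames(truth$calls)),
         mask = mask)
  })
}

#' Estimate a WGA error model from degraded vs truth matrices
#'
#' Method-of-moments inversion of the error channel: the miss rate over
#' all cells, the drop-out rate over called true heterozygotes, and the
#' drop-in/reversal rates over called true homozygotes.  A rate whose
#' denominator class is empty is reported as `NA` (undefined), never 0.
#'
#' @param degraded,truth Aligned genotype matrices.
#' @return A `wga_error_model` with estimated rates (`locus_dispersion`
#'   is not estimated and is returned as 0).
#' @export
estimate_error_model <- function(degraded, truth) {
  stopifnot(identical(dim(degraded$calls), dim(truth$calls)))
  if (anyNA(truth$calls))
    stop("truth matrix contains NO_CALL")
  g <- truth$calls; o <- degraded$calls
  n_total <- length(g)
  miss <- is.na(o)
  het_called <- g == 1L & !miss
  hom_called <- g != 1L & !miss
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  m <- wga_error_model()
  m$miss_rate <- rate(sum(miss), n_total)
  m$ado_rate <- rate(sum(het_called & o != 1L), sum(het_called))
  m$hetgain_rate <- rate(sum(hom_called & o == 1L), sum(hom_called))
  m$reversal_rate <- rate(sum(hom_called & o == (2L - g) & o != 1L),
                          sum(hom_called))
  m$name <- "estimated"
  m
}

#' Export an error mask as a long table
#'
#' @param mask Category matrix from [inject_wga_errors()].
#' @param keep Categories to keep (default: everything but "correct").
#' @return Data frame (sample_id, locus_id, category).
#' @export
mask_as_table <- function(mask, keep = setdiff(MASK_LEVELS, "correct")) {
  idx <- which(matrix(mask %in% keep, nrow(mask)), arr.ind = TRUE)
  data.frame(sample_id = rownames(mask)[idx[, 1]],
             locus_id = colnames(mask)[idx[, 2]],
             category = mask[idx], stringsAsFactors = FALSE)
}
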