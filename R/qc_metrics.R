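# QC metrics: error taxonomy against a reference, replicate
# concordance, the binomial locus-effect test, call-rate/error-rate
# correlation and the quality-score threshold sweep.
#
# Throughout, loci where the reference is NO_CALL are excluded from
# every denominator: a no-call where the reference provided a genotype
# is a failure to provide the correct call, but a reference no-call
# tells us nothing.

#' Classify one observed call against the reference
#'
#' @param ref Reference dosage (0/1/2; must not be NA).
#' @param obs Observed dosage (0/1/2 or NA).
#' @return One of "correct", "no_call", "allele_dropout", "het_gain",
#'   "hom_reversal".  Vectorised.
#' @export
classify_call <- function(ref, obs) {
  if (anyNA(ref)) stop("reference must be called at classified loci")
  out <- character(length(ref))
  out[is.na(obs)] <- "no_call"
  idx <- !is.na(obs)
  r <- ref[idx]; o <- obs[idx]
  cls <- ifelse(o == r, "correct",
         ifelse(r == 1L, "allele_dropout",
         ifelse(o == 1L, "het_gain", "hom_reversal")))
  out[idx] <- cls
  out
}

#' Tally errors of one sample against a reference
#'
#' Computes the full error taxonomy over reference-called loci and the
#' three headline rates: `call_rate` (calls / reference-called loci),
#' `error_rate` (errors / calls, i.e. relative to the number of calls
#' the method provided) and `correct_prop` (correct calls /
#' reference-called loci).
#'
#' @param ref,obs Aligned [genotype_matrix()] objects.
#' @param sample Sample id or index (defaults to the first sample of
#'   `obs`).
#' @return A list of class `error_tally` with counts `n_ref_called`,
#'   `n_called`, `n_correct`, `n_ado`, `n_hetgain`, `n_homrev`,
#'   `n_nocall_vs_ref` and the three rates.
#' @export
error_tally <- function(ref, obs, sample = 1L) {
  stopifnot(identical(ref$loci$locus_id, obs$loci$locus_id))
  if (is.character(sample)) sample <- match(sample, rownames(obs$calls))
  rs <- if (nrow(ref$calls) == 1L) 1L else sample
  r <- ref$calls[rs, ]
  o <- obs$calls[sample, ]
  keep <- !is.na(r)
  if (!any(keep)) stop("no overlapping reference-called loci")
  cls <- classify_call(r[keep], o[keep])
  n <- table(factor(cls, levels = MASK_LEVELS))
  t <- list(n_ref_called = sum(keep),
            n_called = sum(cls != "no_call"),
            n_correct = unname(n[["correct"]]),
            n_ado = unname(n[["allele_dropout"]]),
            n_hetgain = unname(n[["het_gain"]]),
            n_homrev = unname(n[["hom_reversal"]]),
            n_nocall_vs_ref = unname(n[["no_call"]]))
  stopifnot(t$n_called == t$n_correct + t$n_ado + t$n_hetgain + t$n_homrev,
            t$n_ref_called == t$n_called + t$n_nocall_vs_ref)
  t$call_rate <- t$n_called / t$n_ref_called
  t$error_rate <- if (t$n_called > 0)
    (t$n_ado + t$n_hetgain + t$n_homrev) / t$n_called else NA_real_
  t$correct_prop <- t$n_correct / t$n_ref_called
  class(t) <- "error_tally"
  t
}

#' Tally every sample of a matrix against the reference
#'
#' @param ref,obs Aligned genotype matrices (`ref` either one
#'   consensus row or per-sample rows).
#' @return Data frame with one row per sample: counts and rates of
#'   [error_tally()].
#' @export
tally_all <- function(ref, obs) {
  rows <- lapply(seq_len(nrow(obs$calls)), function(i) {
    t <- error_tally(ref, obs, i)
    data.frame(sample_id = rownames(obs$calls)[i],
               as.data.frame(unclass(t)), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Replicate concordance summary
#'
#' For each locus, counts how many replicates provided any call, and
#' (against a reference) how many provided an erroneous call; reports
#' the fractions of loci covered by all replicates, at least two, and
#' any replicate -- and the same trio for erroneous calls.
#'
#' @param replicates List of aligned single-sample (or identically
#'   shaped) genotype matrices.
#' @param ref Optional reference matrix for the error accounting.
#' @return A list of class `concordance_summary`: `k`, `n_loci`,
#'   `call_counts`, `f_all`, `f_atleast2`, `f_any`, and when `ref` is
#'   given, `err_counts`, `e_all`, `e_atleast2`, `e_any`.
#' @export
replicate_concordance <- function(replicates, ref = NULL) {
  stopifnot(length(replicates) >= 2)
  k <- length(replicates)
  base <- replicates[[1]]
  for (r in replicates[-1])
    if (!identical(r$loci$locus_id, base$loci$locus_id))
      stop("replicates must share locus ordering")
  call_mat <- vapply(replicates, function(r) colSums(!is.na(r$calls)) > 0,
                     logical(ncol(base$calls)))
  # single-sample replicates: a locus is "covered" if that sample called
  if (nrow(base$calls) == 1L)
    call_mat <- vapply(replicates, function(r) !is.na(r$calls[1L, ]),
                       logical(ncol(base$calls)))
  counts <- rowSums(call_mat)
  n_loci <- length(counts)
  out <- list(k = k, n_loci = n_loci, call_counts = counts,
              f_all = mean(counts == k),
              f_atleast2 = mean(counts >= 2),
              f_any = mean(counts >= 1))
  if (!is.null(ref)) {
    rrow <- ref$calls[1L, ]
    err_mat <- vapply(replicates, function(r) {
      o <- r$calls[1L, ]
      !is.na(rrow) & !is.na(o) & o != rrow
    }, logical(ncol(base$calls)))
    ec <- rowSums(err_mat)
    out$err_counts <- ec
    out$e_all <- mean(ec == k)
    out$e_atleast2 <- mean(ec >= 2)
    out$e_any <- mean(ec >= 1)
  }
  stopifnot(out$f_all <= out$f_atleast2 + 1e-12,
            out$f_atleast2 <= out$f_any + 1e-12)
  class(out) <- "concordance_summary"
  out
}

#' Expected replicate concordance under a locus-homogeneous binomial
#'
#' If calls land on loci independently with a common success rate `p`
#' (no locus-specific effect), the expected numbers of loci covered by
#' all `k`, at least 2, and any replicate follow directly from the
#' binomial distribution.
#'
#' @param p_mean Mean per-replicate call (or error) rate.
#' @param k Number of replicates.
#' @param n_loci Number of loci.
#' @return Named list `all`, `atleast2`, `any` of expected locus counts.
#' @export
expected_binomial_concordance <- function(p_mean, k, n_loci) {
  stopifnot(p_mean >= 0, p_mean <= 1, k >= 2)
  list(all = n_loci * p_mean^k,
       atleast2 = n_loci * (1 - stats::pbinom(1, k, p_mean)),
       any = n_loci * (1 - (1 - p_mean)^k))
}

#' Paired t-test for a locus-specific effect
#'
#' Compares, across methods, the observed numbers of loci covered in
#' all / at least 2 / any replicate against their binomial
#' expectations, as paired fractions of the locus count.  Under
#' locus-homogeneity the mean paired difference is zero.
#'
#' @param observed,expected Numeric vectors of paired method-level
#'   counts (same order), e.g. the "all replicates" counts.
#' @param n_loci Locus count used to scale counts to fractions.
#' @return `htest`-like list: `statistic`, `df`, `p_value`, `conf_int`
#'   (95% CI of the mean difference, as fractions), `mean_diff`.
#' @export
locus_effect_test <- function(observed, expected, n_loci) {
  stopifnot(length(observed) == length(expected))
  if (length(observed) < 2) stop("need at least 2 paired method values")
  d <- (observed - expected) / n_loci
  if (stats::sd(d) == 0) {
    # degenerate exact agreement: no evidence against the null
    return(list(statistic = 0, df = length(d) - 1, p_value = 1,
                conf_int = c(0, 0), mean_diff = mean(d)))
  }
  tt <- stats::t.test(d)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, conf_int = as.numeric(tt$conf.int),
       mean_diff = unname(tt$estimate))
}

#' Correlation between call rate and error rate
#'
#' @param call_rate,error_rate Paired per-method (or per-replicate)
#'   rates.
#' @return List `r`, `p_value`, `n`.
#' @export
callrate_error_correlation <- function(call_rate, error_rate) {
  stopifnot(length(call_rate) == length(error_rate))
  if (length(call_rate) < 3) stop("need at least 3 points")
  if (stats::sd(call_rate) == 0 || stats::sd(error_rate) == 0)
    stop("zero variance in call or error rates; correlation undefined")
  ct <- stats::cor.test(call_rate, error_rate, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(call_rate))
}

#' Quality-score threshold sweep
#'
#' For each candidate threshold, removing all calls below it removes a
#' fraction of the erroneous calls and retains a fraction of the
#' correct calls.  Reports the sweep and the threshold maximising
#' (errors removed - correct calls lost).
#'
#' @param quality Numeric vector of per-call quality scores.
#' @param is_error Logical vector: is the call erroneous?
#' @param thresholds Candidate thresholds (default: 0 to 1 by 0.01).
#' @return List with `curve` (data frame threshold / error_removal /
#'   correct_retention) and `best_threshold`; `error_removal` is `NA`
#'   throughout when there are no errors.
#' @export
quality_threshold_curve <- function(quality, is_error,
                                    thresholds = seq(0, 1, by = 0.01)) {
  stopifnot(length(quality) == length(is_error))
  keep <- !is.na(quality)
  quality <- quality[keep]; is_error <- is_error[keep]
  n_err <- sum(is_error); n_ok <- sum(!is_error)
  removal <- vapply(thresholds, function(th)
    if (n_err == 0) NA_real_ else mean(quality[is_error] < th), 0)
  retention <- vapply(thresholds, function(th)
    if (n_ok == 0) NA_real_ else mean(quality[!is_error] >= th), 0)
  curve <- data.frame(threshold = thresholds, error_removal = removal,
                      correct_retention = retention)
  best <- if (n_err == 0) NA_real_ else
    thresholds[which.max(removal - (1 - retention))]
  list(curve = curve, best_threshold = best)
}
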