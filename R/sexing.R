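# Sexing from SNP genotypes.
#
# The 50K panel carries no Y-specific loci; sex is inferred by
# comparing X-chromosome heterozygosity to autosomal heterozygosity.
# A male (one X copy, coded homozygous) should show essentially no
# heterozygous X calls, while a female's X looks like an autosome.
# Allele drop-out erodes heterozygosity everywhere, which is why
# heavy-drop-out amplification chemistries missex females as males.

#' Autosomal and X heterozygosity of one sample
#'
#' @param genotypes A [genotype_matrix()].
#' @param sample Sample id or index.
#' @return List `autosomal_het`, `x_het`, `n_auto_called`,
#'   `n_x_called`; the X rate is `NA` when no X locus is called.
#' @export
het_rates <- function(genotypes, sample = 1L) {
  if (is.character(sample)) sample <- match(sample, rownames(genotypes$calls))
  g <- genotypes$calls[sample, ]
  x <- is_x_locus(genotypes)
  auto_called <- !is.na(g) & !x
  x_called <- !is.na(g) & x
  if (!any(auto_called)) stop("no called autosomal loci")
  list(autosomal_het = mean(g[auto_called] == 1L),
       x_het = if (any(x_called)) mean(g[x_called] == 1L) else NA_real_,
       n_auto_called = sum(auto_called),
       n_x_called = sum(x_called))
}

#' Call sex from heterozygosity rates
#'
#' MALE when X heterozygosity falls below `ratio_threshold` times the
#' autosomal rate (with at least `min_x_loci` called X loci); FEMALE
#' when it does not; UNDETERMINED when the X is too sparsely called or
#' autosomal heterozygosity is zero.  The threshold is a ratio, not an
#' absolute level, so it is insensitive to the panel's allele-frequency
#' spectrum.
#'
#' @param rates Output of [het_rates()].
#' @param ratio_threshold X/autosomal heterozygosity ratio below which
#'   a sample is called male.
#' @param min_x_loci Minimum number of called X loci for a male call.
#' @return "MALE", "FEMALE" or "UNDETERMINED".
#' @export
call_sex <- function(rates, ratio_threshold = 0.2, min_x_loci = 50) {
  if (is.na(rates$x_het) || rates$autosomal_het == 0) return("UNDETERMINED")
  if (rates$x_het < ratio_threshold * rates$autosomal_het) {
    if (rates$n_x_called >= min_x_loci) "MALE" else "UNDETERMINED"
  } else {
    "FEMALE"
  }
}

#' Sex every sample of a matrix
#'
#' @param genotypes A [genotype_matrix()].
#' @param ratio_threshold,min_x_loci See [call_sex()].
#' @return Data frame (sample_id, autosomal_het, x_het, n_x_called,
#'   sex_call).
#' @export
sex_table <- function(genotypes, ratio_threshold = 0.2, min_x_loci = 50) {
  rows <- lapply(seq_len(nrow(genotypes$calls)), function(i) {
    r <- het_rates(genotypes, i)
    data.frame(sample_id = rownames(genotypes$calls)[i],
               autosomal_het = r$autosomal_het, x_het = r$x_het,
               n_x_called = r$n_x_called,
               sex_call = call_sex(r, ratio_threshold, min_x_loci),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
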