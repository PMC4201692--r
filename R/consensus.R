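# Consensus reference from replicate runs of unamplified DNA.

#' Build a consensus genotype matrix from replicates
#'
#' Per cell, the modal non-missing call is adopted when its
#' multiplicity reaches `min_agree` and it is the unique mode;
#' otherwise a no-call is generated.  With the default `min_agree = 2`
#' a lone call among no-calls is conservatively discarded; set
#' `min_agree = 1` to adopt any single call (the "any replicate"
#' accounting).
#'
#' @param replicates List of at least two aligned [genotype_matrix()]
#'   objects (identical sample and locus order).
#' @param min_agree Minimum multiplicity of the modal call.
#' @return A [genotype_matrix()] of consensus calls.
#' @export
build_consensus <- function(replicates, min_agree = 2) {
  stopifnot(length(replicates) >= 2, min_agree >= 1)
  ref <- replicates[[1]]
  for (r in replicates[-1]) {
    if (!identical(dim(r$calls), dim(ref$calls)) ||
        !identical(r$loci$locus_id, ref$loci$locus_id) ||
        !identical(rownames(r$calls), rownames(ref$calls)))
      stop("replicates must share sample and locus ordering")
  }
  counts <- lapply(0:2, function(gt) {
    Reduce(`+`, lapply(replicates, function(r) {
      (!is.na(r$calls) & r$calls == gt) + 0L
    }))
  })
  n0 <- counts[[1]]; n1 <- counts[[2]]; n2 <- counts[[3]]
  top <- pmax(n0, n1, n2)
  n_at_top <- (n0 == top) + (n1 == top) + (n2 == top)
  modal <- matrix(NA_integer_, nrow(ref$calls), ncol(ref$calls))
  modal[n0 == top] <- 0L
  modal[n1 == top] <- 1L
  modal[n2 == top] <- 2L
  ok <- top >= min_agree & n_at_top == 1L
  out <- matrix(NA_integer_, nrow(ref$calls), ncol(ref$calls))
  out[ok] <- modal[ok]
  genotype_matrix(out, ref$loci, rownames(ref$calls))
}
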