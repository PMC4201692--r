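# Direct genomic values and the profit-style selection index.
#
# A DGV is the sum over loci of the per-locus additive marker effect
# times the allele-B dosage; the index combines the trait DGVs with
# economic weights on an affine published scale.  Marker effects are
# exogenous inputs here (simulated or user-supplied) -- the package
# does not estimate them.

#' Compute direct genomic values
#'
#' @param genotypes A fully imputed [genotype_matrix()] (no missing
#'   calls allowed; impute first).
#' @param effects A `marker_effect_set` whose rows align with the loci.
#' @return Numeric matrix, samples x traits.
#' @export
compute_dgv <- function(genotypes, effects) {
  stopifnot(inherits(effects, "marker_effect_set"))
  g <- genotypes$calls
  if (anyNA(g))
    stop("genotypes contain missing calls; impute before computing DGV")
  if (nrow(effects$effects) != ncol(g))
    stop("marker effects do not align with the loci")
  dgv <- g %*% effects$effects
  dimnames(dgv) <- list(rownames(g), effects$trait_names)
  dgv
}

#' Combine trait DGVs into a selection index
#'
#' Each trait DGV is standardised over the evaluated cohort, weighted,
#' summed, and mapped onto the published scale
#' `index_offset + index_scale * sum`.  A trait with zero cohort
#' variance carries no ranking information and is skipped with a
#' warning.
#'
#' @param dgv Samples x traits matrix from [compute_dgv()].
#' @param effects The `marker_effect_set` holding weights and scale.
#' @return Named numeric vector of per-sample index values (points).
#' @export
compute_index <- function(dgv, effects) {
  stopifnot(ncol(dgv) == length(effects$index_weights))
  z <- matrix(0, nrow(dgv), ncol(dgv))
  for (t in seq_len(ncol(dgv))) {
    s <- stats::sd(dgv[, t])
    if (s == 0 || nrow(dgv) < 2) {
      warning("trait ", t, " has zero cohort variance; skipped in the index")
      next
    }
    z[, t] <- (dgv[, t] - mean(dgv[, t])) / s
  }
  idx <- effects$index_offset +
    effects$index_scale * as.vector(z %*% effects$index_weights)
  names(idx) <- rownames(dgv)
  idx
}

#' Concordance between embryo- and calf-derived merit
#'
#' @param embryo_index,calf_index Paired per-animal index vectors
#'   (same order), at least 3 pairs.
#' @param top_k Size of the head-of-ranking overlap (default: top 10%
#'   rounded up).
#' @return List `pearson_r`, `p_value`, `mean_abs_divergence` (index
#'   points), `sd_abs_divergence`, `spearman_rho`, `top_k`,
#'   `top_k_overlap`.
#' @export
compare_merit <- function(embryo_index, calf_index,
                          top_k = ceiling(length(calf_index) / 10)) {
  stopifnot(length(embryo_index) == length(calf_index))
  if (length(calf_index) < 3) stop("need at least 3 paired animals")
  if (stats::sd(embryo_index) == 0 || stats::sd(calf_index) == 0)
    stop("zero variance in an index; correlation undefined")
  ct <- stats::cor.test(embryo_index, calf_index, method = "pearson")
  rho <- stats::cor(embryo_index, calf_index, method = "spearman")
  d <- abs(embryo_index - calf_index)
  top_e <- order(embryo_index, decreasing = TRUE)[seq_len(top_k)]
  top_c <- order(calf_index, decreasing = TRUE)[seq_len(top_k)]
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value,
       mean_abs_divergence = mean(d), sd_abs_divergence = stats::sd(d),
       spearman_rho = rho, top_k = top_k,
       top_k_overlap = length(intersect(top_e, top_c)) / top_k)
}

#' Read / write a long-format marker-effect TSV
#'
#' Columns `locus_id`, `trait`, `effect`; index metadata travels in
#' `# key value` comment lines (weights as comma-separated per-trait
#' values).
#'
#' @param path File path.
#' @param loci Locus map fixing row order.
#' @return A `marker_effect_set`.
#' @export
read_marker_effects <- function(path, loci) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    tok <- strsplit(sub("^#\\s*", "", ml), "\\s+")[[1]]
    if (length(tok) >= 2) meta[[tok[1]]] <- tok[2]
  }
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("locus_id", "trait", "effect") %in% names(df)))
  traits <- unique(df$trait)
  eff <- matrix(0, nrow(loci), length(traits),
                dimnames = list(loci$locus_id, traits))
  li <- match(df$locus_id, loci$locus_id)
  if (anyNA(li)) stop("marker-effect table names loci absent from the map")
  eff[cbind(li, match(df$trait, traits))] <- df$effect
  w <- if (!is.null(meta$index_weights))
    as.numeric(strsplit(meta$index_weights, ",")[[1]]) else rep(1, length(traits))
  structure(list(effects = eff, trait_names = traits,
                 index_weights = rep_len(w, length(traits)),
                 index_scale = as.numeric(meta$index_scale %||% 100),
                 index_offset = as.numeric(meta$index_offset %||% 1000)),
            class = "marker_effect_set")
}

#' @rdname read_marker_effects
#' @param effects A `marker_effect_set`.
#' @export
write_marker_effects <- function(effects, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# index_weights %s",
                       paste(effects$index_weights, collapse = ",")),
               sprintf("# index_scale %s", effects$index_scale),
               sprintf("# index_offset %s", effects$index_offset)), con)
  df <- data.frame(locus_id = rep(rownames(effects$effects),
                                  ncol(effects$effects)),
                   trait = rep(effects$trait_names,
                               each = nrow(effects$effects)),
                   effect = as.vector(effects$effects))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
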