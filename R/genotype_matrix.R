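# Core container: a samples x loci grid of biallelic SNP calls.
#
# Calls are stored as allele-B dosage: 0 = HOM_A, 1 = HET, 2 = HOM_B,
# NA = NO_CALL.  Loci live in a map data frame (locus_id, chromosome,
# position_bp, allele_a, allele_b, cM); the X chromosome carries the
# label "X", autosomes "1".."29".

#' Construct a genotype matrix
#'
#' Bundles a dosage matrix with its locus map and optional per-call
#' quality scores.  Dosage counts copies of allele B: 0 (homozygous A),
#' 1 (heterozygous), 2 (homozygous B); `NA` is a no-call.
#'
#' @param calls Integer matrix, samples in rows, loci in columns; entries
#'   0/1/2/NA.  Row names are taken as sample ids if `sample_ids` is
#'   missing.
#' @param loci Data frame with columns `locus_id`, `chromosome`,
#'   `position_bp`, `allele_a`, `allele_b` and optionally `cM`.
#' @param sample_ids Character vector of unique sample ids.
#' @param quality Optional numeric matrix of per-call quality scores in
#'   \[0,1\], same dimensions as `calls`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, loci, sample_ids = rownames(calls),
                            quality = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sample_ids)) {
    sample_ids <- if (nrow(calls) > 0) paste0("S", seq_len(nrow(calls))) else character(0)
  }
  sample_ids <- as.character(sample_ids)
  loci <- validate_loci(loci)
  if (nrow(calls) != length(sample_ids))
    stop("number of rows of `calls` must equal length of `sample_ids`")
  if (ncol(calls) != nrow(loci))
    stop("number of columns of `calls` must equal number of loci")
  if (anyDuplicated(sample_ids))
    stop("sample ids must be unique")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("calls must be 0, 1, 2 or NA")
  dimnames(calls) <- list(sample_ids, loci$locus_id)
  if (!is.null(quality)) {
    quality <- as.matrix(quality)
    if (!identical(dim(quality), dim(calls)))
      stop("`quality` must have the same dimensions as `calls`")
    qv <- quality[!is.na(quality)]
    if (length(qv) && (any(qv < 0) || any(qv > 1)))
      stop("quality scores must lie in [0, 1]")
    dimnames(quality) <- dimnames(calls)
  }
  structure(list(calls = calls, loci = loci, quality = quality),
            class = "genotype_matrix")
}

# Locus map validation shared by constructor and the io layer.
validate_loci <- function(loci) {
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  required <- c("locus_id", "chromosome", "position_bp")
  miss <- setdiff(required, names(loci))
  if (length(miss))
    stop("locus map lacks column(s): ", paste(miss, collapse = ", "))
  loci$locus_id <- as.character(loci$locus_id)
  loci$chromosome <- normalise_chromosome(loci$chromosome)
  loci$position_bp <- as.integer(loci$position_bp)
  if (anyDuplicated(loci$locus_id))
    stop("locus ids must be unique")
  if (nrow(loci) && any(is.na(loci$position_bp) | loci$position_bp < 1L))
    stop("positions must be positive integers (1-based)")
  if (is.null(loci$allele_a)) loci$allele_a <- rep("A", nrow(loci))
  if (is.null(loci$allele_b)) loci$allele_b <- rep("B", nrow(loci))
  rownames(loci) <- NULL
  loci
}

# Cattle convention: chromosome "30" is an alias for "X" on input;
# internally the label is always "X".
normalise_chromosome <- function(chr) {
  chr <- as.character(chr)
  chr[chr == "30"] <- "X"
  ok <- chr %in% c(as.character(1:29), "X")
  if (any(!ok))
    stop("chromosome labels must be in {1..29, X}; offending: ",
         paste(unique(chr[!ok]), collapse = ", "))
  chr
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%d chromosome(s))\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$loci$chromosome))))
  cr <- mean(!is.na(x$calls))
  cat(sprintf("  call rate %.3f; quality scores %s\n",
              if (length(x$calls)) cr else NA_real_,
              if (is.null(x$quality)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Subset a genotype matrix by sample and/or locus
#'
#' @param x A `genotype_matrix`.
#' @param samples Sample ids or indices (default: all).
#' @param loci Locus ids or indices (default: all).
#' @return A `genotype_matrix` restricted to the selection.
#' @export
gm_subset <- function(x, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(x$calls)) else samples
  li <- if (is.null(loci)) seq_len(ncol(x$calls)) else loci
  if (is.character(si)) si <- match(si, rownames(x$calls))
  if (is.character(li)) li <- match(li, x$loci$locus_id)
  if (anyNA(si)) stop("unknown sample id in subset")
  if (anyNA(li)) stop("unknown locus id in subset")
  genotype_matrix(x$calls[si, li, drop = FALSE], x$loci[li, , drop = FALSE],
                  rownames(x$calls)[si],
                  if (is.null(x$quality)) NULL else x$quality[si, li, drop = FALSE])
}

#' Extract the dosage matrix
#'
#' @param x A `genotype_matrix`.
#' @return Integer matrix of allele-B dosages (NA = no-call).
#' @export
gm_dosage <- function(x) x$calls

#' Which loci are autosomal / X-linked
#'
#' @param x A `genotype_matrix` or locus map data frame.
#' @return Logical vector along the loci.
#' @export
is_x_locus <- function(x) {
  loci <- if (inherits(x, "genotype_matrix")) x$loci else x
  loci$chromosome == "X"
}

#' Construct a pedigree table
#'
#' @param individual_id,sire_id,dam_id Character vectors; `NA` (or "0")
#'   marks an unknown parent.
#' @param sex Character vector with entries "MALE", "FEMALE" or "UNKNOWN".
#' @return A data frame of class `pedigree_table`.
#' @export
pedigree_table <- function(individual_id, sire_id = NA, dam_id = NA,
                           sex = "UNKNOWN") {
  n <- length(individual_id)
  ped <- data.frame(individual_id = as.character(individual_id),
                    sire_id = as.character(rep_len(sire_id, n)),
                    dam_id = as.character(rep_len(dam_id, n)),
                    sex = as.character(rep_len(sex, n)),
                    stringsAsFactors = FALSE)
  ped$sire_id[ped$sire_id %in% c("0", "")] <- NA_character_
  ped$dam_id[ped$dam_id %in% c("0", "")] <- NA_character_
  if (anyDuplicated(ped$individual_id))
    stop("pedigree individual ids must be unique")
  if (!all(ped$sex %in% c("MALE", "FEMALE", "UNKNOWN")))
    stop("sex must be MALE, FEMALE or UNKNOWN")
  known_sire <- !is.na(ped$sire_id)
  known_dam <- !is.na(ped$dam_id)
  if (any(known_sire & !(ped$sire_id %in% ped$individual_id)))
    stop("known sire absent from pedigree")
  if (any(known_dam & !(ped$dam_id %in% ped$individual_id)))
    stop("known dam absent from pedigree")
  if (any(ped$individual_id == ped$sire_id, na.rm = TRUE) ||
      any(ped$individual_id == ped$dam_id, na.rm = TRUE))
    stop("an individual cannot be its own parent")
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

#' Genomic DNA content of an embryo biopsy
#'
#' A diploid mammalian cell carries about 6 pg of genomic DNA, so a
#' typical 15-cell trophoblast biopsy yields on the order of 90 pg --
#' roughly a thousandth of the input most amplification kits expect,
#' which is why whole-genome amplification is unavoidable.
#'
#' @param n_cells Number of biopsied cells.
#' @param pg_per_cell Genomic DNA per diploid cell, picograms.
#' @return DNA quantity in picograms.
#' @export
biopsy_dna_pg <- function(n_cells = 15, pg_per_cell = 6) {
  stopifnot(n_cells >= 0, pg_per_cell >= 0)
  n_cells * pg_per_cell
}
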