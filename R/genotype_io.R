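# Text I/O: PLINK .ped/.map and GenomeStudio-style final reports.
#
# PED/MAP is the lingua franca for SNP-array genotypes; the final-report
# dialect is what genotyping services export (it carries the per-call
# GC quality score that the array platform produces).

GT_MISSING_ALLELE <- "0"

#' Read a PLINK .ped/.map pair
#'
#' The .map may have the classic 4 columns (chromosome, locus id, cM,
#' position) or an extended 6-column variant whose last two columns name
#' allele A and allele B, fixing the dosage orientation.  With a
#' 4-column map the two alleles observed at each locus are assigned in
#' lexicographic order (A first), and monomorphic loci get a "B"
#' placeholder second allele.  Chromosome "30" is read as "X".
#'
#' @param ped_path,map_path Paths to the .ped and .map files.
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `pedigree` (a [pedigree_table()] built from the six leading .ped
#'   columns; sex code 1 is MALE, 2 FEMALE, anything else UNKNOWN).
#' @export
read_plink <- function(ped_path, map_path) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_tok <- strsplit(trimws(map_lines), "[ \t]+")
  ncol_map <- unique(lengths(map_tok))
  if (length(ncol_map) != 1 || !ncol_map %in% c(4L, 6L))
    stop(".map must have 4 or 6 whitespace-separated columns on every row")
  mp <- do.call(rbind, map_tok)
  loci <- data.frame(locus_id = mp[, 2], chromosome = mp[, 1],
                     position_bp = as.integer(mp[, 4]),
                     cM = suppressWarnings(as.numeric(mp[, 3])),
                     stringsAsFactors = FALSE)
  has_alleles <- ncol_map == 6L
  if (has_alleles) {
    loci$allele_a <- mp[, 5]
    loci$allele_b <- mp[, 6]
  }
  n_loci <- nrow(loci)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n_samp <- length(ped_lines)
  a1 <- matrix(NA_character_, n_samp, n_loci)
  a2 <- matrix(NA_character_, n_samp, n_loci)
  meta <- matrix(NA_character_, n_samp, 6)
  for (i in seq_len(n_samp)) {
    tok <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * n_loci)
      stop(sprintf(".ped line %d has %d fields; expected %d (6 + 2 x %d loci)",
                   i, length(tok), 6 + 2 * n_loci, n_loci))
    meta[i, ] <- tok[1:6]
    g <- tok[-(1:6)]
    a1[i, ] <- g[c(TRUE, FALSE)]
    a2[i, ] <- g[c(FALSE, TRUE)]
  }
  all_seen <- unique(c(a1, a2))
  bad <- setdiff(all_seen, c("A", "C", "G", "T", "B", "0", "-", NA))
  if (length(bad))
    stop("unknown allele character(s) in .ped: ", paste(bad, collapse = ", "))

  if (!has_alleles) {
    loci$allele_a <- rep("A", n_loci)
    loci$allele_b <- rep("B", n_loci)
    for (j in seq_len(n_loci)) {
      obs <- sort(setdiff(unique(c(a1[, j], a2[, j])), c("0", "-", NA)))
      if (length(obs) >= 1) loci$allele_a[j] <- obs[1]
      if (length(obs) >= 2) loci$allele_b[j] <- obs[2]
    }
  }

  calls <- matrix(NA_integer_, n_samp, n_loci)
  for (j in seq_len(n_loci)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 %in% c("0", "-") | x2 %in% c("0", "-")
    valid <- c(loci$allele_a[j], loci$allele_b[j])
    stray <- setdiff(unique(c(x1[!miss], x2[!miss])), valid)
    if (length(stray))
      stop(sprintf("locus %s carries allele(s) %s not in its map alleles {%s}",
                   loci$locus_id[j], paste(stray, collapse = ","),
                   paste(valid, collapse = ",")))
    d <- (x1 == loci$allele_b[j]) + (x2 == loci$allele_b[j])
    d[miss] <- NA_integer_
    calls[, j] <- as.integer(d)
  }

  sex <- rep("UNKNOWN", n_samp)
  sex[meta[, 5] == "1"] <- "MALE"
  sex[meta[, 5] == "2"] <- "FEMALE"
  ped <- pedigree_table(meta[, 2], meta[, 3], meta[, 4], sex)
  gm <- genotype_matrix(calls, loci, sample_ids = meta[, 2])
  list(genotypes = gm, pedigree = ped)
}

#' Write a PLINK .ped/.map pair
#'
#' Emits the extended 6-column .map (with allele columns) so that
#' `read_plink(write_plink(x))` restores the matrix bit-exactly.
#' No-calls become "0 0"; the X chromosome is written as "X".
#'
#' @param genotypes A [genotype_matrix()].
#' @param pedigree Optional [pedigree_table()] covering all samples; if
#'   absent, samples are written as founders of unknown sex.
#' @param out_prefix Output path prefix; `<prefix>.ped` and
#'   `<prefix>.map` are created.
#' @return Invisibly, the two file paths.
#' @export
write_plink <- function(genotypes, pedigree = NULL, out_prefix) {
  loci <- genotypes$loci
  cm <- if (is.null(loci$cM)) rep(0, nrow(loci)) else ifelse(is.na(loci$cM), 0, loci$cM)
  map_path <- paste0(out_prefix, ".map")
  ped_path <- paste0(out_prefix, ".ped")
  writeLines(paste(loci$chromosome, loci$locus_id, format(cm, trim = TRUE,
                                                          scientific = FALSE),
                   loci$position_bp, loci$allele_a, loci$allele_b),
             map_path)

  ids <- rownames(genotypes$calls)
  if (is.null(pedigree)) {
    pedigree <- pedigree_table(ids)
  }
  idx <- match(ids, pedigree$individual_id)
  if (anyNA(idx)) stop("pedigree does not cover all samples")
  sex_code <- c(MALE = "1", FEMALE = "2", UNKNOWN = "0")[pedigree$sex[idx]]
  sire <- ifelse(is.na(pedigree$sire_id[idx]), "0", pedigree$sire_id[idx])
  dam <- ifelse(is.na(pedigree$dam_id[idx]), "0", pedigree$dam_id[idx])

  n <- nrow(genotypes$calls)
  lines <- character(n)
  for (i in seq_len(n)) {
    d <- genotypes$calls[i, ]
    # HET is written allele_a allele_b, so output order is deterministic
    x1 <- ifelse(!is.na(d) & d == 2L, loci$allele_b, loci$allele_a)
    x2 <- ifelse(!is.na(d) & d >= 1L, loci$allele_b, loci$allele_a)
    x1[is.na(d)] <- GT_MISSING_ALLELE
    x2[is.na(d)] <- GT_MISSING_ALLELE
    lines[i] <- paste(c("FAM", ids[i], sire[i], dam[i], sex_code[i], "-9",
                        as.vector(rbind(x1, x2))), collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a GenomeStudio-style final report
#'
#' Tab-separated, an optional "[Header]" block ending at a "[Data]"
#' marker, then a header row with at least the columns `SNP Name`,
#' `Sample ID`, `Allele1`, `Allele2` and optionally `GC Score`
#' (suffixed variants such as "Allele1 - AB" are accepted).  Alleles
#' are A/B design alleles; "-" is a no-call.
#'
#' @param path Path to the report file.
#' @param loci Optional locus map data frame fixing locus order;
#'   otherwise loci appear in order of first appearance with placeholder
#'   positions.
#' @return A [genotype_matrix()] with quality scores attached when the
#'   report carries a GC Score column.
#' @export
read_final_report <- function(path, loci = NULL) {
  lines <- readLines(path)
  data_at <- which(trimws(lines) == "[Data]")
  if (length(data_at)) lines <- lines[-seq_len(data_at[1])]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("final report has no data section")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  find_col <- function(name) {
    hit <- which(hdr == name | startsWith(hdr, paste0(name, " ")))
    if (!length(hit))
      stop(sprintf("column '%s' not found; columns present: %s",
                   name, paste(hdr, collapse = ", ")))
    hit[1]
  }
  c_snp <- find_col("SNP Name"); c_samp <- find_col("Sample ID")
  c_a1 <- find_col("Allele1"); c_a2 <- find_col("Allele2")
  c_gc <- tryCatch(find_col("GC Score"), error = function(e) NA_integer_)

  tok <- strsplit(lines[-1], "\t", fixed = TRUE)
  get <- function(k) vapply(tok, function(t) t[k], "")
  snp <- get(c_snp); samp <- get(c_samp)
  al1 <- get(c_a1); al2 <- get(c_a2)
  gc <- if (is.na(c_gc)) NULL else suppressWarnings(as.numeric(get(c_gc)))

  if (is.null(loci)) {
    ids <- unique(snp)
    loci <- data.frame(locus_id = ids, chromosome = "1",
                       position_bp = seq_along(ids),
                       allele_a = "A", allele_b = "B",
                       stringsAsFactors = FALSE)
  } else {
    loci <- validate_loci(loci)
  }
  samples <- unique(samp)
  li <- match(snp, loci$locus_id)
  if (anyNA(li)) stop("report contains loci absent from the supplied map")
  si <- match(samp, samples)
  miss <- al1 == "-" | al2 == "-"
  bad <- setdiff(unique(c(al1[!miss], al2[!miss])), c("A", "B"))
  if (length(bad))
    stop("final report alleles must be A/B/-; found: ", paste(bad, collapse = ", "))
  d <- (al1 == "B") + (al2 == "B")
  d[miss] <- NA_integer_
  calls <- matrix(NA_integer_, length(samples), nrow(loci))
  calls[cbind(si, li)] <- as.integer(d)
  quality <- NULL
  if (!is.null(gc)) {
    quality <- matrix(NA_real_, length(samples), nrow(loci))
    quality[cbind(si, li)] <- gc
  }
  genotype_matrix(calls, loci, sample_ids = samples, quality = quality)
}

#' Write a GenomeStudio-style final report
#'
#' One row per (locus, sample) pair with A/B alleles and the call's
#' GC score (blank when absent).
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_final_report <- function(genotypes, path) {
  ids <- rownames(genotypes$calls)
  loci <- genotypes$loci
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("[Header]",
               "Processing Date\tsynthetic",
               sprintf("Num SNPs\t%d", nrow(loci)),
               sprintf("Num Samples\t%d", length(ids)),
               "[Data]",
               "SNP Name\tSample ID\tAllele1 - AB\tAllele2 - AB\tGC Score"),
             con)
  for (i in seq_along(ids)) {
    d <- genotypes$calls[i, ]
    a1 <- ifelse(is.na(d), "-", ifelse(d >= 1L, ifelse(d == 1L, "A", "B"), "A"))
    a2 <- ifelse(is.na(d), "-", ifelse(d >= 1L, "B", "A"))
    q <- if (is.null(genotypes$quality)) rep("", length(d)) else
      ifelse(is.na(genotypes$quality[i, ]), "",
             format(genotypes$quality[i, ], digits = 6))
    writeLines(paste(loci$locus_id, ids[i], a1, a2, q, sep = "\t"), con)
  }
  invisible(path)
}

#' Read / write a standalone pedigree TSV
#'
#' Four tab-separated columns: individual, sire, dam, sex
#' (MALE/FEMALE/UNKNOWN or 1/2/0); "0" or empty parent fields mean
#' unknown.
#'
#' @param path File path.
#' @return A [pedigree_table()].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  need <- c("individual_id", "sire_id", "dam_id", "sex")
  if (!all(need %in% names(df)))
    stop("pedigree TSV needs columns: ", paste(need, collapse = ", "))
  sx <- df$sex
  sx[sx == "1"] <- "MALE"; sx[sx == "2"] <- "FEMALE"; sx[sx == "0"] <- "UNKNOWN"
  pedigree_table(df$individual_id, df$sire_id, df$dam_id, sx)
}

#' @rdname read_pedigree
#' @param pedigree A [pedigree_table()].
#' @export
write_pedigree <- function(pedigree, path) {
  out <- as.data.frame(pedigree)
  out$sire_id[is.na(out$sire_id)] <- "0"
  out$dam_id[is.na(out$dam_id)] <- "0"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
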