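#' Genotype matrix container
#'
#' A `genotype_matrix` couples an accessions x SNPs dosage matrix (alt-allele
#' counts 0/1/2, `NA` for missing calls) with a variant table. Dosage rows are
#' named by accession id and columns by SNP id; the variant table is a tibble
#' with columns `id`, `chrom`, `pos` (1-based), `ref`, `alt`, sorted by
#' (chrom, pos).
#'
#' @param dosages Numeric matrix, accessions x SNPs, values in {0, 1, 2, NA}.
#'   Must carry rownames (accession ids) and colnames (SNP ids).
#' @param variants Tibble with columns `id`, `chrom`, `pos`, `ref`, `alt`;
#'   one row per dosage column, in column order.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, variants) {
  stopifnot(is.matrix(dosages))
  variants <- as_tibble(variants)
  req <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants))) {
    abort(paste0("variants must have columns: ", paste(req, collapse = ", ")))
  }
  if (ncol(dosages) > 0 &&
      (is.null(rownames(dosages)) || is.null(colnames(dosages)))) {
    abort("dosages must have accession rownames and SNP colnames")
  }
  if (ncol(dosages) == 0) {
    dimnames(dosages) <- list(rownames(dosages), character(0))
  }
  if (anyDuplicated(rownames(dosages))) abort("duplicate accession ids")
  if (ncol(dosages) != nrow(variants)) {
    abort("variant table does not match dosage columns")
  }
  if (ncol(dosages) > 0 && !identical(colnames(dosages), variants$id)) {
    abort("dosage colnames must equal variants$id, in order")
  }
  if (any(variants$pos < 1)) abort("positions must be >= 1")
  key <- paste(variants$chrom, variants$pos)
  if (anyDuplicated(key)) abort("duplicate (chrom, pos) in variant table")
  ord <- order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(nrow(variants)))) {
    abort("variants must be sorted by (chrom, pos)")
  }
  bad <- dosages[!is.na(dosages) & !(dosages %in% c(0, 1, 2))]
  if (length(bad) > 0) abort("dosages must be 0, 1, 2 or NA")
  structure(list(dosages = dosages, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d accessions x %d SNPs (%.1f%% missing)\n",
    nrow(x$dosages), ncol(x$dosages),
    100 * mean(is.na(x$dosages))
  ))
  chroms <- unique(x$variants$chrom)
  cat("  chromosomes:", paste(head(chroms, 8), collapse = ", "),
      if (length(chroms) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Accession ids of a genotype matrix
#' @param gm A `genotype_matrix`.
#' @return Character vector of accession ids.
#' @export
accessions <- function(gm) rownames(gm$dosages)

#' Subset a genotype matrix
#'
#' @param gm A `genotype_matrix`.
#' @param snp_ids Optional character vector of SNP ids to keep (order taken
#'   from the variant table, not from `snp_ids`).
#' @param accession_ids Optional character vector of accessions to keep.
#' @param chrom,start,end Optional region filter (1-based inclusive).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(gm, snp_ids = NULL, accession_ids = NULL,
                             chrom = NULL, start = NULL, end = NULL) {
  keep <- rep(TRUE, nrow(gm$variants))
  if (!is.null(snp_ids)) keep <- keep & gm$variants$id %in% snp_ids
  if (!is.null(chrom)) keep <- keep & gm$variants$chrom == chrom
  if (!is.null(start)) keep <- keep & gm$variants$pos >= start
  if (!is.null(end)) keep <- keep & gm$variants$pos <= end
  d <- gm$dosages[, keep, drop = FALSE]
  v <- gm$variants[keep, , drop = FALSE]
  if (!is.null(accession_ids)) {
    d <- d[rownames(d) %in% accession_ids, , drop = FALSE]
  }
  genotype_matrix(d, v)
}
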