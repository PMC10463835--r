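#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (via vcfR) and converts diploid GT calls to
#' alt-allele dosages: `0/0` -> 0, `0/1` or `1/0` -> 1, `1/1` -> 2,
#' `./.` -> missing. Phased separators (`|`) are accepted. Multiallelic
#' records are excluded with a warning giving their count.
#'
#' @param path Path to a VCF file.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (file.size(path) == 0) abort("empty VCF file")
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("VCF parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no variant records")
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  if (any(multi)) {
    warn(sprintf("excluded %d multiallelic record(s)", sum(multi)))
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  dos <- apply(gt, c(1, 2), gt_to_dosage)
  ids <- fix$ID
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix$CHROM[noid], "_", fix$POS[noid])
  variants <- tibble(
    id = ids, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, ]
  dos <- t(dos[ord, , drop = FALSE])
  colnames(dos) <- variants$id
  genotype_matrix(dos, variants)
}

gt_to_dosage <- function(gt) {
  if (is.na(gt)) return(NA_real_)
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_real_)
  a <- suppressWarnings(as.integer(alleles))
  if (length(a) != 2 || anyNA(a) || any(a > 1)) return(NA_real_)
  sum(a)
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits unphased GT calls (`0/0`, `0/1`, `1/1`, `./.`); round-trips through
#' [read_vcf()] bit-exactly.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", accessions(gm)), collapse = "\t")
  )
  d <- gm$dosages
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_codes[d[ok] + 1]
  v <- gm$variants
  body <- paste(
    v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write an annotation tibble as GFF3
#'
#' @param annotation Tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(annotation, path) {
  lines <- c(
    "##gff-version 3",
    paste(annotation$chrom, "sim", "gene", annotation$start, annotation$end,
          ".", annotation$strand, ".",
          paste0("ID=", annotation$gene_id, ";Name=", annotation$gene_id),
          sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read gene records from a GFF3 file
#'
#' Imports via rtracklayer and keeps `gene` features (all features if none
#' are typed `gene`), returning 1-based inclusive spans.
#'
#' @param path Path to a GFF3 file.
#' @return Tibble (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @export
read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if ("type" %in% names(S4Vectors::mcols(gr)) &&
      any(S4Vectors::mcols(gr)$type == "gene")) {
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  }
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  tibble(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}
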