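#' Per-SNP allele statistics
#'
#' Computes the alt-allele frequency over non-missing calls, the minor
#' allele frequency `min(p, 1 - p)`, and the missing-call fraction for every
#' SNP. SNPs with all calls missing get `NA` frequencies and are flagged.
#'
#' @param gm A [genotype_matrix()].
#' @return Tibble (`id`, `chrom`, `pos`, `alt_freq`, `maf`, `missing_frac`,
#'   `all_missing`).
#' @export
allele_stats <- function(gm) {
  d <- gm$dosages
  if (ncol(d) == 0 || nrow(d) == 0) abort("empty genotype matrix")
  n_called <- unname(colSums(!is.na(d)))
  alt <- unname(colSums(d, na.rm = TRUE))
  p <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  gm$variants %>%
    select("id", "chrom", "pos") %>%
    mutate(
      alt_freq = p,
      maf = pmin(p, 1 - p),
      missing_frac = unname(colMeans(is.na(d))),
      all_missing = n_called == 0
    )
}

#' Filter variants on MAF and missingness
#'
#' Keeps SNPs whose minor allele frequency is strictly greater than
#' `maf_min` and whose missing fraction is strictly less than `max_missing`
#' (the conventions "MAF > 0.05" and "missing rate < 20%"). SNP order is
#' preserved; kept/dropped counts are attached as attribute `"filter_stats"`.
#'
#' @param gm A [genotype_matrix()].
#' @param maf_min MAF threshold (strict `>`), default 0.05.
#' @param max_missing Missing-fraction threshold (strict `<`), default 0.2.
#' @return Filtered [genotype_matrix()].
#' @export
filter_variants <- function(gm, maf_min = 0.05, max_missing = 0.2) {
  stopifnot(maf_min >= 0, maf_min <= 1, max_missing >= 0, max_missing <= 1)
  st <- allele_stats(gm)
  keep <- !st$all_missing & st$maf > maf_min & st$missing_frac < max_missing
  if (!any(keep)) warn("all SNPs removed by the variant filters")
  out <- genotype_matrix(gm$dosages[, keep, drop = FALSE],
                         gm$variants[keep, , drop = FALSE])
  attr(out, "subpop") <- attr(gm, "subpop")
  attr(out, "filter_stats") <- list(kept = sum(keep),
                                    dropped = sum(!keep))
  out
}

#' Variant-stats report with kept flags
#'
#' @inheritParams filter_variants
#' @return [allele_stats()] tibble plus a logical `kept` column under the
#'   same strict thresholds as [filter_variants()].
#' @export
variant_report <- function(gm, maf_min = 0.05, max_missing = 0.2) {
  allele_stats(gm) %>%
    mutate(kept = !.data$all_missing & .data$maf > maf_min &
             .data$missing_frac < max_missing)
}
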