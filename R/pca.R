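#' Principal components of the genotype matrix
#'
#' LD-prunes the markers first (see [ld_prune()]), mean-imputes missing
#' dosages, centers each SNP at twice its allele frequency and standardizes
#' by its binomial standard deviation, then eigendecomposes the accession
#' covariance matrix. Variance fractions are eigenvalues over their total.
#'
#' @param gm A [genotype_matrix()].
#' @param n_components Number of PCs to return (default 3, the usual GWAS
#'   covariate set).
#' @param prune Logical; LD-prune before the decomposition (default TRUE).
#' @param window_bp,step,r2_max Pruning parameters, see [ld_prune()].
#' @return Object of class `geno_pca`: list with `scores` (tibble:
#'   `accession`, `PC1`, ...), `var_frac`, `n_snps_used`.
#' @export
pca_genotypes <- function(gm, n_components = 3, prune = TRUE,
                          window_bp = 5e4, step = 5, r2_max = 0.2) {
  if (ncol(gm$dosages) == 0) abort("empty genotype matrix")
  use <- gm
  if (prune) {
    pr <- ld_prune(gm, window_bp = window_bp, step = step, r2_max = r2_max)
    use <- subset_genotypes(gm, snp_ids = pr$kept_ids)
  }
  d <- use$dosages
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1 & !is.na(p)
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  for (j in seq_len(ncol(d))) {
    d[is.na(d[, j]), j] <- 2 * p[j]
  }
  z <- sweep(d, 2, 2 * p, "-")
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), "/")
  C <- tcrossprod(z) / ncol(z)
  ee <- eigen(C, symmetric = TRUE)
  rank <- sum(ee$values > 1e-10)
  if (n_components > rank) {
    warn(sprintf("n_components reduced to rank %d", rank))
    n_components <- rank
  }
  scores <- ee$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(pmax(ee$values[seq_len(n_components)], 0)),
         n_components, n_components)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  structure(list(
    scores = bind_cols(tibble(accession = accessions(use)),
                       as_tibble(scores)),
    var_frac = pmax(ee$values, 0)[seq_len(n_components)] /
      sum(pmax(ee$values, 0)),
    n_snps_used = ncol(z)
  ), class = "geno_pca")
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf(
    "<geno_pca> %d accessions, %d SNPs used; var explained: %s\n",
    nrow(x$scores), x$n_snps_used,
    paste(sprintf("%.1f%%", 100 * x$var_frac), collapse = ", ")
  ))
  invisible(x)
}
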