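#' Simple-matching kinship matrix
#'
#' `K[i, j]` is the fraction of loci at which accessions i and j carry the
#' identical genotype category (0, 1 or 2), over the loci where both are
#' non-missing. The diagonal is 1 by construction and entries lie in
#' \[0, 1\].
#'
#' @param gm A [genotype_matrix()].
#' @return Matrix of class `c("kinship_matrix", "matrix")`, accession ids as
#'   dimnames.
#' @export
kinship_simple_matching <- function(gm) {
  d <- gm$dosages
  if (nrow(d) < 2) abort("need >= 2 accessions")
  called <- !is.na(d)
  matches <- matrix(0, nrow(d), nrow(d))
  for (g in 0:2) {
    ind <- (d == g) & called
    ind[!called] <- FALSE
    matches <- matches + tcrossprod(ind * 1)
  }
  joint <- tcrossprod(called * 1)
  if (any(joint == 0)) {
    abort("accession pair with zero jointly genotyped loci; kinship undefined")
  }
  K <- matches / joint
  dimnames(K) <- list(accessions(gm), accessions(gm))
  class(K) <- c("kinship_matrix", "matrix")
  K
}

# Floor the eigenvalues of K at `floor_ev` so downstream mixed models get a
# positive-semidefinite covariance; simple-matching K can go slightly
# indefinite after pairwise missing-data exclusion.
bend_psd <- function(K, floor_ev = 1e-6) {
  ee <- eigen(K, symmetric = TRUE)
  if (min(ee$values) >= floor_ev) return(K)
  v <- pmax(ee$values, floor_ev)
  K2 <- ee$vectors %*% (v * t(ee$vectors))
  dimnames(K2) <- dimnames(K)
  K2
}
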