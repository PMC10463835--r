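#' Tajima's D over a genotype region
#'
#' The classical neutrality statistic contrasting mean pairwise nucleotide
#' differences with the segregating-sites estimator of theta, computed from
#' diploid genotypes in the allele-count convention of VCF-based tools:
#' each accession contributes two chromosomes, so `n = 2 * accessions`, a
#' site's alternate-allele count is the sum of its dosages, and the mean
#' pairwise difference at a site with counts (c, n - c) is
#' `c * (n - c) / choose(n, 2)`. Sites with missing calls use their own
#' called chromosome count for the pairwise term; the normalizing constants
#' use the full `n` (documented approximation for low missingness).
#'
#' @param gm A [genotype_matrix()], typically restricted to a region via
#'   [subset_genotypes()].
#' @return List with `D`, `S` (segregating sites), `pi` (sum of per-site
#'   mean pairwise differences), `n_chromosomes`.
#' @export
tajimas_d <- function(gm) {
  d <- gm$dosages
  if (nrow(d) < 2) abort("need >= 2 accessions (4 chromosomes)")
  n <- 2 * nrow(d)
  if (n < 4) abort("need >= 4 chromosomes")
  n_called <- 2 * colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  seg <- alt > 0 & alt < n_called
  S <- sum(seg)
  if (S == 0) abort("no segregating sites in region; D undefined")
  cc <- alt[seg]
  nn <- n_called[seg]
  pi <- sum(cc * (nn - cc) / choose(nn, 2))

  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  D <- (pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(D = D, S = S, pi = pi, n_chromosomes = n)
}
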