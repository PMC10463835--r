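#' Simulate block-LD genotypes
#'
#' Generates a diploid dosage matrix with block-structured linkage
#' disequilibrium and subpopulation allele-frequency divergence. Each LD
#' block has one founder frequency; every accession draws two founder
#' haplotype indicators per block from its subpopulation's Balding-Nichols
#' frequency, and each SNP inside the block copies the founder indicator
#' with a per-SNP flip probability tuned so that the mean pairwise dosage
#' r-squared within a block is approximately `within_block_r2`. Blocks are
#' mutually independent, so between-block r-squared is at chance level.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_matrix()]; the subpopulation assignment is attached
#'   as attribute `"subpop"` (integer vector named by accession).
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  withr::with_seed(cfg$seed, simulate_genotypes_impl(cfg))
}

simulate_genotypes_impl <- function(cfg) {
  n <- cfg$n_accessions
  acc_ids <- sprintf("ACC%03d", seq_len(n))
  subpop <- rep(seq_len(cfg$n_subpops), length.out = n)
  names(subpop) <- acc_ids

  # flip probability: at founder frequency 1/2 the allele-level correlation
  # between two block mates is (1 - 2*eps)^2, so r^2 = (1 - 2*eps)^4
  q <- cfg$within_block_r2^(1 / 4)
  eps <- (1 - q) / 2

  chrom_names <- paste0("chr", seq_len(cfg$n_chroms))
  dos_blocks <- list()
  var_blocks <- list()
  for (ci in seq_len(cfg$n_chroms)) {
    m <- cfg$snps_per_chrom
    pos <- sort(sample.int(cfg$chrom_length_bp, m, replace = FALSE))
    block <- (pos - 1) %/% cfg$ld_block_size_bp
    dos <- matrix(NA_real_, n, m)
    for (b in unique(block)) {
      idx <- which(block == b)
      k <- length(idx)
      p0 <- runif(1, 0.25, 0.75)
      pk <- if (cfg$fst > 0) {
        a <- p0 * (1 - cfg$fst) / cfg$fst
        bb <- (1 - p0) * (1 - cfg$fst) / cfg$fst
        pmin(pmax(stats::rbeta(cfg$n_subpops, a, bb), 0.02), 0.98)
      } else {
        rep(p0, cfg$n_subpops)
      }
      p_acc <- pk[subpop]
      h1 <- rbinom(n, 1, p_acc)
      h2 <- rbinom(n, 1, p_acc)
      if (eps > 0) {
        f1 <- matrix(rbinom(n * k, 1, eps), n, k)
        f2 <- matrix(rbinom(n * k, 1, eps), n, k)
        a1 <- abs(matrix(h1, n, k) - f1)
        a2 <- abs(matrix(h2, n, k) - f2)
      } else {
        a1 <- matrix(h1, n, k)
        a2 <- matrix(h2, n, k)
      }
      dos[, idx] <- a1 + a2
    }
    if (cfg$missing_rate > 0) {
      miss <- matrix(runif(n * m) < cfg$missing_rate, n, m)
      dos[miss] <- NA_real_
    }
    ids <- sprintf("%s_%d", chrom_names[ci], pos)
    colnames(dos) <- ids
    rownames(dos) <- acc_ids
    dos_blocks[[ci]] <- dos
    var_blocks[[ci]] <- tibble(
      id = ids, chrom = chrom_names[ci], pos = pos,
      ref = sample(c("A", "C", "G", "T"), m, replace = TRUE),
      alt = NA_character_
    )
  }
  variants <- bind_rows(var_blocks)
  variants$alt <- vapply(variants$ref, function(r) {
    sample(setdiff(c("A", "C", "G", "T"), r), 1)
  }, character(1))
  gm <- genotype_matrix(do.call(cbind, dos_blocks), variants)
  attr(gm, "subpop") <- subpop
  gm
}
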