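# Shared fixtures built in code.

# Small config for fast generator tests
small_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_accessions = 60, n_subpops = 4, n_chroms = 2,
                   snps_per_chrom = 120, chrom_length_bp = 1e7,
                   ld_block_size_bp = 5e5, missing_rate = 0.02,
                   n_qtl = 0, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Hand-built genotype matrix from a dosage matrix (one chromosome,
# positions 1000, 2000, ...)
toy_gm <- function(dos, chrom = "chr1", pos = NULL) {
  n <- nrow(dos)
  m <- ncol(dos)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  ids <- sprintf("%s_%d", chrom, pos)
  rownames(dos) <- sprintf("ACC%03d", seq_len(n))
  colnames(dos) <- ids
  genotype_matrix(dos, tibble::tibble(
    id = ids, chrom = chrom, pos = pos,
    ref = rep("A", m), alt = rep("T", m)
  ))
}

# Write a small handcrafted VCF, returning its path
write_test_vcf <- function(lines, dir = tempdir()) {
  path <- tempfile("test_", fileext = ".vcf", tmpdir = dir)
  writeLines(lines, path)
  path
}

vcf_header <- function(samples) {
  c("##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

# Balanced two-way phenotype table from an effects specification
balanced_obs <- function(geno_eff, year_eff, gxe = NULL, reps = 2,
                         noise_sd = 0, seed = 1) {
  ng <- length(geno_eff)
  ny <- length(year_eff)
  if (is.null(gxe)) gxe <- matrix(0, ng, ny)
  withr::with_seed(seed, {
    grid <- expand.grid(g = seq_len(ng), y = seq_len(ny), r = seq_len(reps))
    tibble::tibble(
      accession = sprintf("G%02d", grid$g),
      year = grid$y,
      rep = grid$r,
      value = geno_eff[grid$g] + year_eff[grid$y] +
        gxe[cbind(grid$g, grid$y)] + rnorm(nrow(grid), 0, noise_sd)
    )
  })
}
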