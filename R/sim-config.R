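#' Simulation configuration
#'
#' Bundles every knob of the synthetic genotype/phenotype generator. The
#' defaults emulate the study design the pipeline targets: ~300 accessions in
#' 10 admixed subpopulations, block-structured LD, two trial years with five
#' replicates, and a handful of pleiotropic QTLs acting on the 12 measured
#' spike-component traits.
#'
#' Variance components `var_G`, `var_GxE`, `var_e` (and the year main-effect
#' variance `var_year`) are the generating truth of the two-way
#' genotype x year model and are expressed on the scale of a reference trait
#' with mean 100 (see the methods vignette); `trait_cor` is the fraction of
#' each component shared across the 12 traits, which makes spike components
#' co-vary the way parts of one spike do.
#'
#' @param n_accessions Number of accessions.
#' @param n_subpops Number of subpopulations (admixture groups).
#' @param n_chroms Number of chromosomes.
#' @param snps_per_chrom SNPs per chromosome.
#' @param chrom_length_bp Chromosome length in bp.
#' @param ld_block_size_bp LD block size in bp; SNPs within one block are
#'   correlated, blocks are independent.
#' @param within_block_r2 Target mean pairwise r-squared within a block, in
#'   \[0, 1\].
#' @param missing_rate Per-call missingness probability.
#' @param fst Subpopulation allele-frequency divergence (Balding-Nichols).
#' @param n_qtl Number of QTLs planted on the component traits.
#' @param qtl_h2 Per-QTL fraction of single-observation phenotypic variance;
#'   recycled to `n_qtl`. Their sum must stay below 1.
#' @param n_years,n_reps Trial years and replicates per accession x year.
#' @param var_G,var_year,var_GxE,var_e Generating variance components
#'   (genotype, year, genotype x year, residual), all >= 0.
#' @param trait_cor Fraction of each variance component shared across the 12
#'   component traits, in \[0, 1\].
#' @param region_coupling Probability that an accession's geographic region
#'   equals its subpopulation's home region (metadata generator).
#' @param seed Integer seed; every generator output is deterministic in it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_accessions = 300,
                       n_subpops = 10,
                       n_chroms = 3,
                       snps_per_chrom = 1000,
                       chrom_length_bp = 5e7,
                       ld_block_size_bp = 5e5,
                       within_block_r2 = 0.8,
                       missing_rate = 0.02,
                       fst = 0.1,
                       n_qtl = 5,
                       qtl_h2 = 0.05,
                       n_years = 2,
                       n_reps = 5,
                       var_G = 4,
                       var_year = 1,
                       var_GxE = 2,
                       var_e = 5,
                       trait_cor = 0.5,
                       region_coupling = 0.8,
                       seed = 1L) {
  cfg <- list(
    n_accessions = as.integer(n_accessions), n_subpops = as.integer(n_subpops),
    n_chroms = as.integer(n_chroms), snps_per_chrom = as.integer(snps_per_chrom),
    chrom_length_bp = chrom_length_bp, ld_block_size_bp = ld_block_size_bp,
    within_block_r2 = within_block_r2, missing_rate = missing_rate, fst = fst,
    n_qtl = as.integer(n_qtl),
    qtl_h2 = rep_len(qtl_h2, max(as.integer(n_qtl), 1L)),
    n_years = as.integer(n_years), n_reps = as.integer(n_reps),
    var_G = var_G, var_year = var_year, var_GxE = var_GxE, var_e = var_e,
    trait_cor = trait_cor, region_coupling = region_coupling,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_accessions", "n_subpops", "n_chroms", "snps_per_chrom",
              "n_years", "n_reps")
  for (f in counts) {
    if (cfg[[f]] < 1) abort(paste0(f, " must be >= 1"))
  }
  fracs <- c("within_block_r2", "missing_rate", "fst", "trait_cor",
             "region_coupling")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort(paste0(f, " must be in [0, 1]"))
  }
  if (cfg$n_qtl < 0) abort("n_qtl must be >= 0")
  if (cfg$n_qtl > 0 && sum(cfg$qtl_h2) >= 1) {
    abort("sum of qtl_h2 must be < 1")
  }
  for (f in c("var_G", "var_year", "var_GxE", "var_e")) {
    if (cfg[[f]] < 0) abort(paste0(f, " must be >= 0"))
  }
  if (cfg$ld_block_size_bp < 1 || cfg$chrom_length_bp < 1) {
    abort("lengths must be positive")
  }
  invisible(cfg)
}

# Reference mean against which the generating variance components are scaled:
# a trait with mean `mu` carries components (mu / 100)^2 * configured.
SIM_MU_REF <- 100

#' Catalog of the 12 measured spike-component traits
#'
#' Names, nominal units and generating means of the measured traits
#' (weights in mg, lengths in mm so that all means are comfortably positive
#' on the simulator's multiplicative scale). Two traits are counts and are
#' rounded to integers by the phenotype generator.
#'
#' @return Tibble with columns `trait`, `unit`, `mean`, `is_count`.
#' @export
measured_trait_catalog <- function() {
  tibble(
    trait = c("spike_length", "spike_weight", "grain_weight", "awn_weight",
              "chaff_weight", "grain_number", "spikelet_number",
              "rachis_weight", "spikelet_weight", "grain_number_spikelet",
              "chaff_weight_spikelet", "grain_weight_spikelet"),
    unit = c("mm", "mg", "mg", "mg", "mg", "count", "count", "mg", "mg",
             "count/spikelet", "mg", "mg"),
    mean = c(100, 3500, 2000, 300, 1200, 55, 20, 200, 150, 2.8, 50, 100),
    is_count = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE,
                 FALSE, FALSE, FALSE, FALSE)
  )
}
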