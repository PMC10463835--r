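#' Plant QTL ground truth on the component traits
#'
#' Chooses `n_qtl` reasonably common SNPs and assigns each a signed additive
#' effect on one to three of the 12 measured component traits. Effects are
#' expressed as the fraction of single-observation phenotypic variance the
#' QTL explains (`qtl_h2` in the config). QTLs touch component traits only;
#' any ratio-trait signal downstream emerges mechanistically from its
#' numerator and denominator.
#'
#' @param gm A [genotype_matrix()].
#' @param cfg A [sim_config()].
#' @param effects Optional tibble (`snp_id`, `trait`, `h2`, `sign`) giving
#'   the full assignment explicitly; when supplied, `n_qtl`/`qtl_h2` in the
#'   config are ignored. Use this to plant, e.g., antagonistic effects of
#'   one QTL on a ratio's numerator and denominator.
#' @return A list of class `qtl_truth` with `effects` (tibble), and `subpop`
#'   (copied from the genotype attribute when present).
#' @export
make_qtl_truth <- function(gm, cfg, effects = NULL) {
  traits <- measured_trait_catalog()$trait
  if (is.null(effects)) {
    effects <- withr::with_seed(cfg$seed + 1000L, {
      p <- colMeans(gm$dosages, na.rm = TRUE) / 2
      maf <- pmin(p, 1 - p)
      eligible <- gm$variants$id[maf >= 0.1]
      if (cfg$n_qtl > length(eligible)) {
        abort("not enough common SNPs to place QTLs")
      }
      if (cfg$n_qtl == 0) {
        tibble(snp_id = character(), trait = character(),
               h2 = numeric(), sign = numeric())
      } else {
        ids <- sample(eligible, cfg$n_qtl)
        purrr::map2_dfr(ids, cfg$qtl_h2, function(id, h2) {
          k <- sample(1:3, 1)
          tibble(snp_id = id, trait = sample(traits, k),
                 h2 = h2, sign = sample(c(-1, 1), k, replace = TRUE))
        })
      }
    })
  } else {
    effects <- as_tibble(effects)
  }
  if (!all(effects$snp_id %in% gm$variants$id)) {
    abort("qtl snp_id absent from the genotype matrix")
  }
  if (!all(effects$trait %in% traits)) {
    abort("qtl effects must target measured component traits")
  }
  structure(list(effects = effects, subpop = attr(gm, "subpop")),
            class = "qtl_truth")
}

#' Simulate replicated multi-year phenotypes
#'
#' Generates the 12 measured spike-component traits for every accession x
#' year x replicate cell under the two-way model
#' value = mu + genotype + year + genotype x year + error, with QTL dosage
#' effects added to the genotype term of their assigned traits. Trait values
#' are produced as `mu_t * exp(x / 100)` where `x` carries the additive
#' effects, which guarantees strict positivity while keeping the
#' observed-scale variance components essentially equal to the configured
#' ones for a trait with mean 100 (and scaled by `(mu_t/100)^2` otherwise).
#' A configurable fraction (`trait_cor`) of each variance component is
#' shared across traits so that spike components co-vary; the genotype term
#' is built from genome-wide SNP effects so that its covariance follows the
#' realized kinship. Count traits are rounded to integers.
#'
#' @param gm A [genotype_matrix()].
#' @param truth A [make_qtl_truth()] result.
#' @param cfg A [sim_config()].
#' @return Long tibble (`accession`, `trait`, `year`, `rep`, `value`).
#' @export
simulate_phenotypes <- function(gm, truth, cfg) {
  validate_sim_config(cfg)
  if (!all(truth$effects$snp_id %in% gm$variants$id)) {
    abort("qtl snp_id absent from the genotype matrix")
  }
  withr::with_seed(cfg$seed + 2000L, simulate_phenotypes_impl(gm, truth, cfg))
}

simulate_phenotypes_impl <- function(gm, truth, cfg) {
  cat_tbl <- measured_trait_catalog()
  traits <- cat_tbl$trait
  nt <- length(traits)
  n <- nrow(gm$dosages)
  acc <- accessions(gm)
  rho <- cfg$trait_cor
  v0 <- cfg$var_G + cfg$var_GxE + cfg$var_e

  # polygenic accession term from genome-wide SNP effects, standardized to
  # realized variance var_G; one shared vector + one own vector per trait.
  # SNPs in LD blocks holding a planted QTL are excluded from the polygenic
  # basis so the QTL's variance share is not confounded by background
  # effects on the same block.
  poly_cols <- rep(TRUE, ncol(gm$dosages))
  if (nrow(truth$effects) > 0) {
    v <- gm$variants
    for (qid in unique(truth$effects$snp_id)) {
      qi <- match(qid, v$id)
      poly_cols[v$chrom == v$chrom[qi] &
                  abs(v$pos - v$pos[qi]) <= cfg$ld_block_size_bp] <- FALSE
    }
  }
  poly_vec <- function() {
    d <- gm$dosages[, poly_cols, drop = FALSE]
    d[is.na(d)] <- 0
    u <- rnorm(ncol(d))
    g <- as.numeric(d %*% u)
    g <- g - mean(g)
    s <- sd(g)
    if (s < 1e-12) rnorm(n) else g / s
  }
  g_shared <- poly_vec()
  G <- vapply(seq_len(nt), function(t) {
    sqrt(cfg$var_G) * (sqrt(rho) * g_shared + sqrt(1 - rho) * poly_vec())
  }, numeric(n))

  # QTL dosage effects (mean-imputed dosages for the genetic value); h2 is
  # the fraction of the trait's total single-observation variance, so the
  # effect is inflated by 1 / (1 - sum of h2 on that trait)
  if (nrow(truth$effects) > 0) {
    h2_tot <- tapply(truth$effects$h2, truth$effects$trait, sum)
    for (k in seq_len(nrow(truth$effects))) {
      e <- truth$effects[k, ]
      d <- gm$dosages[, e$snp_id]
      d[is.na(d)] <- mean(d, na.rm = TRUE)
      vd <- var(d)
      if (vd < 1e-12) next
      beta <- e$sign * sqrt(e$h2 / (1 - h2_tot[[e$trait]]) * v0 / vd)
      ti <- match(e$trait, traits)
      G[, ti] <- G[, ti] + beta * (d - mean(d))
    }
  }

  ny <- cfg$n_years
  nr <- cfg$n_reps
  y_shared <- rnorm(ny)
  Y <- sqrt(cfg$var_year) *
    (sqrt(rho) * matrix(y_shared, ny, nt) +
       sqrt(1 - rho) * matrix(rnorm(ny * nt), ny, nt))
  gy_shared <- matrix(rnorm(n * ny), n * ny, 1)
  GY <- sqrt(cfg$var_GxE) *
    (sqrt(rho) * matrix(gy_shared, n * ny, nt) +
       sqrt(1 - rho) * matrix(rnorm(n * ny * nt), n * ny, nt))

  grid <- tidyr::expand_grid(
    accession = acc, year = seq_len(ny), rep = seq_len(nr)
  )
  ia <- match(grid$accession, acc)
  iy <- grid$year
  igy <- (iy - 1L) * n + ia
  ncell <- nrow(grid)
  e_shared <- rnorm(ncell)
  out <- vector("list", nt)
  for (t in seq_len(nt)) {
    e_t <- sqrt(cfg$var_e) *
      (sqrt(rho) * e_shared + sqrt(1 - rho) * rnorm(ncell))
    x <- G[ia, t] + Y[iy, t] + GY[igy, t] + e_t
    mu <- cat_tbl$mean[t]
    val <- mu * exp(x / SIM_MU_REF)
    if (cat_tbl$is_count[t]) val <- round(val)
    out[[t]] <- mutate(grid, trait = traits[t], value = val)
  }
  bind_rows(out) %>%
    select("accession", "trait", "year", "rep", "value") %>%
    arrange(.data$trait, .data$accession, .data$year, .data$rep)
}
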