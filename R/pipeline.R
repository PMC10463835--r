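#' Pipeline run configuration
#'
#' Collects inputs and stage parameters for [run_pipeline()]. Exactly one
#' of `simulate` (a [sim_config()]) or `paths` (a named list with `vcf`,
#' `phenotypes`, `metadata`, and optionally `gff3`, `expression`) must be
#' given. Stage defaults follow common GWAS practice for this design:
#' MAF > 0.05, missing < 0.2, top 3 PCs, working -log10 p = 5, LD-interval
#' r-squared > 0.1, 5 Mb lead-gap merging, peaks at > 10 SNPs, 500 kb gene
#' windows.
#'
#' @param simulate Optional [sim_config()].
#' @param paths Optional named list of input paths.
#' @param maf_min,max_missing Variant filters.
#' @param n_pcs Number of PC covariates.
#' @param working_neglog10p Working significance threshold.
#' @param clump_r2_min LD threshold joining significant SNPs.
#' @param merge_gap_bp Lead-SNP merge distance.
#' @param min_peak_snps Peak-calling member threshold.
#' @param gene_window_bp Candidate-gene half window.
#' @param n_perm Permutations for the empirical threshold (0 to skip).
#' @param traits Traits to scan; default all 27.
#' @param seed Integer seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(simulate = NULL, paths = NULL,
                       maf_min = 0.05, max_missing = 0.2, n_pcs = 3,
                       working_neglog10p = 5, clump_r2_min = 0.1,
                       merge_gap_bp = 5e6, min_peak_snps = 10,
                       gene_window_bp = 5e5, n_perm = 0,
                       traits = NULL, seed = 1L) {
  if (is.null(simulate) == is.null(paths)) {
    abort("exactly one of `simulate` or `paths` must be given")
  }
  stopifnot(maf_min >= 0, maf_min <= 1, max_missing >= 0, max_missing <= 1,
            n_pcs >= 1, clump_r2_min >= 0, clump_r2_min <= 1,
            merge_gap_bp > 0, min_peak_snps >= 0, gene_window_bp > 0)
  structure(list(
    simulate = simulate, paths = paths, maf_min = maf_min,
    max_missing = max_missing, n_pcs = n_pcs,
    working_neglog10p = working_neglog10p, clump_r2_min = clump_r2_min,
    merge_gap_bp = merge_gap_bp, min_peak_snps = min_peak_snps,
    gene_window_bp = gene_window_bp, n_perm = n_perm, traits = traits,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full mapping pipeline
#'
#' Executes, in order: simulate or read inputs; variant filtering; trait
#' derivation; per-trait variance components, heritability and BLUEs;
#' kinship and PCA; the mixed-model scan per trait; significance
#' thresholds; LD-interval delineation and peak calling; the cross-trait
#' region summary; candidate genes per peak; and, when a gene region is
#' supplied, haplotype assignment and effects. Every stage's output is
#' written as plain TSV/JSON under `out_dir`, with a manifest recording
#' the configuration hash, seed and per-stage row counts. A stage failure
#' aborts with the stage name; files already written are retained.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible list with the in-memory stage results (`genotypes`,
#'   `phenotypes`, `blues`, `heritability`, `kinship`, `pca`, `scans`,
#'   `thresholds`, `peaks`, `regions`, `candidates`, `manifest`).
#' @export
run_pipeline <- function(cfg, out_dir = tempfile("spikegwas_run_")) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  res <- list()
  if (!is.null(cfg$simulate)) {
    sc <- cfg$simulate
    gm <- stage("simulate", simulate_genotypes(sc))
    truth <- stage("simulate", make_qtl_truth(gm, sc))
    pheno <- stage("simulate", simulate_phenotypes(gm, truth, sc))
    meta <- stage("simulate", simulate_metadata(sc, attr(gm, "subpop")))
    ann <- stage("simulate", simulate_annotation(sc))
    expr_tbl <- stage("simulate", simulate_expression(ann, sc))
    res$truth <- truth
    write_vcf(gm, file.path(out_dir, "genotypes.vcf"))
    readr::write_tsv(pheno, file.path(out_dir, "phenotypes.tsv"))
    readr::write_tsv(meta, file.path(out_dir, "metadata.tsv"))
    write_gff3(ann, file.path(out_dir, "annotation.gff3"))
    readr::write_tsv(expr_tbl, file.path(out_dir, "expression.tsv"))
    jsonlite::write_json(truth$effects, file.path(out_dir, "truth.json"))
  } else {
    gm <- stage("read", read_vcf(cfg$paths$vcf))
    pheno <- stage("read", readr::read_tsv(cfg$paths$phenotypes,
                                           show_col_types = FALSE))
    meta <- if (!is.null(cfg$paths$metadata)) {
      readr::read_tsv(cfg$paths$metadata, show_col_types = FALSE)
    }
    ann <- if (!is.null(cfg$paths$gff3)) read_gff3_genes(cfg$paths$gff3)
    expr_tbl <- if (!is.null(cfg$paths$expression)) {
      readr::read_tsv(cfg$paths$expression, show_col_types = FALSE)
    }
  }
  counts$n_accessions <- nrow(gm$dosages)
  counts$n_snps_raw <- ncol(gm$dosages)

  gm <- stage("filter", filter_variants(gm, cfg$maf_min, cfg$max_missing))
  counts$n_snps_filtered <- ncol(gm$dosages)
  readr::write_tsv(variant_report(gm, cfg$maf_min, cfg$max_missing),
                   file.path(out_dir, "variant_report.tsv"))

  pheno27 <- stage("traits", derive_traits(pheno))
  traits <- cfg$traits %||% unique(pheno27$trait)
  counts$n_traits <- length(traits)

  h2_tbl <- stage("heritability", purrr::map_dfr(traits, function(tr) {
    vc <- anova_components(filter(pheno27, .data$trait == tr))
    tibble(trait = tr, var_G = vc$var_G, var_GxE = vc$var_GxE,
           var_e = vc$var_e, H2 = heritability(vc))
  }))
  readr::write_tsv(h2_tbl, file.path(out_dir, "heritability.tsv"))

  blues <- stage("blues", blue_table(pheno27, traits))
  blues <- blues[match(accessions(gm), blues$accession), ]
  readr::write_tsv(blues, file.path(out_dir, "blues.tsv"))

  K <- stage("kinship", kinship_simple_matching(gm))
  readr::write_tsv(as_tibble(unclass(K), rownames = "accession"),
                   file.path(out_dir, "kinship.tsv"))
  pr <- stage("prune", ld_prune(gm))
  pca <- stage("pca", pca_genotypes(gm, n_components = cfg$n_pcs))
  readr::write_tsv(pca$scores, file.path(out_dir, "pca.tsv"))
  S <- cbind(intercept = 1,
             as.matrix(pca$scores[, paste0("PC", seq_len(cfg$n_pcs))]))

  scans <- stage("scan", purrr::map(setNames(traits, traits), function(tr) {
    y <- blues[[tr]]
    association_scan(gm, y, S, K, mode = "approx", trait = tr)
  }))
  for (tr in traits) {
    readr::write_tsv(scans[[tr]],
                     file.path(out_dir, paste0("scan_", tr, ".tsv")))
  }

  perm <- NULL
  if (cfg$n_perm >= 20) {
    perm <- stage("threshold", permutation_threshold(
      gm, blues[[traits[1]]], S, K, n_perm = cfg$n_perm,
      seed = cfg$seed + 5000L
    ))
  }
  thr <- threshold_set(pr$n_independent, perm,
                       working_neglog10p = cfg$working_neglog10p)
  jsonlite::write_json(
    list(bonferroni = thr$bonferroni,
         permutation = if (!is.null(perm)) {
           perm[c("p_threshold", "neglog10p", "n_perm")]
         },
         working_neglog10p = thr$working_neglog10p),
    file.path(out_dir, "thresholds.json"), auto_unbox = TRUE, digits = NA
  )

  peaks_by_trait <- stage("peaks", purrr::map_dfr(traits, function(tr) {
    sig <- filter(scans[[tr]], .data$neglog10p >= cfg$working_neglog10p)
    if (nrow(sig) == 0) return(tibble())
    ivl <- delineate_intervals(sig, gm, r2_min = cfg$clump_r2_min)
    merge_and_call_peaks(ivl, sig, max_lead_gap_bp = cfg$merge_gap_bp,
                         min_snps = cfg$min_peak_snps) %>%
      mutate(trait = tr)
  }))
  counts$n_intervals <- nrow(peaks_by_trait)
  counts$n_peaks <- if ("is_peak" %in% names(peaks_by_trait)) {
    sum(peaks_by_trait$is_peak)
  } else 0L
  if (nrow(peaks_by_trait) > 0) {
    readr::write_tsv(
      peaks_by_trait %>%
        mutate(snps = purrr::map_chr(.data$snps, paste, collapse = ",")) %>%
        mutate(bed_start = .data$start - 1, .after = "end"),
      file.path(out_dir, "peaks.tsv")
    )
  }

  summary_ct <- stage("cross_trait", cross_trait_summary(peaks_by_trait))
  if (nrow(peaks_by_trait) > 0) {
    readr::write_tsv(
      summary_ct$regions %>%
        mutate(traits = purrr::map_chr(.data$traits, paste, collapse = ",")),
      file.path(out_dir, "regions.tsv")
    )
    readr::write_tsv(summary_ct$incidence,
                     file.path(out_dir, "region_trait_matrix.tsv"))
  }

  candidates <- NULL
  if (!is.null(ann) && !is.null(expr_tbl) && nrow(peaks_by_trait) > 0) {
    candidates <- stage("candidates", purrr::map_dfr(
      which(peaks_by_trait$is_peak), function(i) {
        candidate_genes(peaks_by_trait[i, ], ann, expr_tbl,
                        window_bp = cfg$gene_window_bp) %>%
          mutate(peak_id = peaks_by_trait$peak_id[i],
                 trait = peaks_by_trait$trait[i])
      }))
    if (!is.null(candidates) && nrow(candidates) > 0) {
      readr::write_tsv(candidates, file.path(out_dir, "candidate_genes.tsv"))
    }
  }

  manifest <- list(
    package = "spikegwas",
    version = as.character(utils::packageVersion("spikegwas")),
    seed = cfg$seed,
    config_hash = rlang::hash(cfg),
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(c(res, list(
    genotypes = gm, phenotypes = pheno27, metadata = meta,
    heritability = h2_tbl, blues = blues, kinship = K, pca = pca,
    scans = scans, thresholds = thr, peaks = peaks_by_trait,
    regions = summary_ct, candidates = candidates, manifest = manifest,
    out_dir = out_dir
  )))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
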