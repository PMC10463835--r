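#' Delineate LD intervals from significant SNPs
#'
#' Per chromosome, builds a graph on the significant SNPs with an edge
#' wherever pairwise r-squared exceeds `r2_min`; connected components are
#' the intervals, bounded by the min/max member positions (1-based
#' inclusive). LD is computed only among the significant SNPs.
#'
#' @param sig_snps An [association_scan()] tibble already filtered to the
#'   working threshold (columns `snp`, `chrom`, `pos`, `neglog10p`).
#' @param gm The [genotype_matrix()] the scan used.
#' @param r2_min LD edge threshold (strict `>`), default 0.1.
#' @return Tibble (`interval_id`, `chrom`, `start`, `end`, `n_snps`,
#'   `lead_snp`, `lead_pos`, `best_neglog10p`, `snps` (list-column)).
#' @export
delineate_intervals <- function(sig_snps, gm, r2_min = 0.1) {
  if (nrow(sig_snps) == 0) {
    return(tibble(interval_id = character(), chrom = character(),
                  start = integer(), end = integer(), n_snps = integer(),
                  lead_snp = character(), lead_pos = integer(),
                  best_neglog10p = numeric(), snps = list()))
  }
  sig_snps <- arrange(sig_snps, .data$chrom, .data$pos)
  out <- purrr::map_dfr(unique(sig_snps$chrom), function(ch) {
    sub <- filter(sig_snps, .data$chrom == ch)
    idx <- match(sub$snp, gm$variants$id)
    if (anyNA(idx)) abort("significant SNP missing from genotype matrix")
    r2 <- ld_matrix(gm$dosages[, idx, drop = FALSE])
    adj <- !is.na(r2) & r2 > r2_min
    diag(adj) <- TRUE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    purrr::map_dfr(sort(unique(comp)), function(cid) {
      mem <- which(comp == cid)
      lead <- lead_snp_of(sub[mem, ])
      tibble(
        chrom = ch,
        start = min(sub$pos[mem]), end = max(sub$pos[mem]),
        n_snps = length(mem),
        lead_snp = lead$snp, lead_pos = lead$pos,
        best_neglog10p = lead$neglog10p,
        snps = list(sub$snp[mem])
      )
    })
  })
  out %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(interval_id = sprintf("ivl_%03d", row_number()), .before = 1)
}

# most significant SNP; ties broken by smaller position
lead_snp_of <- function(tbl) {
  tbl <- arrange(tbl, desc(.data$neglog10p), .data$pos)
  tbl[1, c("snp", "pos", "neglog10p")]
}

#' Merge adjacent intervals and flag peaks
#'
#' Iteratively merges, per chromosome, adjacent intervals whose lead SNPs
#' lie strictly less than `max_lead_gap_bp` apart (default 5 Mb),
#' re-deriving the lead after every merge, until stable. An interval is
#' flagged as a peak when it holds strictly more than `min_snps`
#' significant SNPs (default 10).
#'
#' @param intervals Output of [delineate_intervals()].
#' @param sig_snps The significant-SNP tibble the intervals were built from
#'   (needed to re-derive leads after merging).
#' @param max_lead_gap_bp Merge threshold on lead-SNP distance (strict
#'   `<`), default 5e6.
#' @param min_snps Peak-calling threshold on member count (strict `>`),
#'   default 10.
#' @return Tibble like `intervals` plus `is_peak`; `interval_id` becomes
#'   `peak_id`.
#' @export
merge_and_call_peaks <- function(intervals, sig_snps,
                                 max_lead_gap_bp = 5e6, min_snps = 10) {
  if (nrow(intervals) == 0) {
    return(mutate(intervals, is_peak = logical()))
  }
  merged <- purrr::map_dfr(unique(intervals$chrom), function(ch) {
    rows <- intervals %>%
      filter(.data$chrom == ch) %>%
      arrange(.data$lead_pos)
    repeat {
      if (nrow(rows) < 2) break
      gaps <- diff(rows$lead_pos)
      hit <- which(gaps < max_lead_gap_bp)
      if (length(hit) == 0) break
      i <- hit[1]
      snps <- union(rows$snps[[i]], rows$snps[[i + 1]])
      sub <- filter(sig_snps, .data$snp %in% snps)
      lead <- lead_snp_of(sub)
      newrow <- tibble(
        chrom = ch,
        start = min(rows$start[i], rows$start[i + 1]),
        end = max(rows$end[i], rows$end[i + 1]),
        n_snps = length(snps),
        lead_snp = lead$snp, lead_pos = lead$pos,
        best_neglog10p = lead$neglog10p,
        snps = list(snps)
      )
      rows <- bind_rows(rows[seq_len(i - 1), ], newrow,
                        rows[-seq_len(i + 1), ]) %>%
        arrange(.data$lead_pos)
    }
    rows
  })
  merged %>%
    select(-dplyr::any_of("interval_id")) %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(peak_id = sprintf("peak_%03d", row_number()),
           is_peak = .data$n_snps > min_snps, .before = 1)
}

#' Collapse peaks across traits into unified regions
#'
#' Overlapping peaks (any shared bp) from different traits are collapsed
#' into one region; the region records its supporting traits, each trait's
#' best -log10 p, and whether it is exclusive to ratio traits.
#'
#' @param peaks_by_trait Tibble concatenating [merge_and_call_peaks()]
#'   outputs with a `trait` column.
#' @param defs Trait definitions ([trait_definitions()]) used to classify
#'   traits as measured or ratio.
#' @param peaks_only Use only rows with `is_peak` (default FALSE: all
#'   intervals).
#' @return List with `regions` (tibble: `region_id`, `chrom`, `start`,
#'   `end`, `n_traits`, `traits`, `ratio_only`) and `incidence` (region x
#'   trait tibble of best -log10 p).
#' @export
cross_trait_summary <- function(peaks_by_trait, defs = trait_definitions(),
                                peaks_only = FALSE) {
  if (nrow(peaks_by_trait) == 0) {
    return(list(regions = tibble(), incidence = tibble()))
  }
  stopifnot("trait" %in% names(peaks_by_trait))
  pk <- peaks_by_trait
  if (peaks_only) pk <- filter(pk, .data$is_peak)
  if (nrow(pk) == 0) {
    return(list(regions = tibble(), incidence = tibble()))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = pk$chrom,
    ranges = IRanges::IRanges(start = pk$start, end = pk$end)
  )
  red <- GenomicRanges::reduce(gr)
  hits <- GenomicRanges::findOverlaps(gr, red)
  region_idx <- integer(nrow(pk))
  region_idx[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  pk$region_idx <- region_idx
  kind <- setNames(defs$kind, defs$trait)
  regions <- pk %>%
    group_by(.data$region_idx) %>%
    summarise(
      chrom = first(.data$chrom),
      start = min(.data$start), end = max(.data$end),
      n_traits = dplyr::n_distinct(.data$trait),
      traits = list(sort(unique(.data$trait))),
      ratio_only = all(kind[unique(.data$trait)] == "ratio"),
      .groups = "drop"
    ) %>%
    arrange(.data$chrom, .data$start) %>%
    mutate(region_id = sprintf("region_%03d", row_number()))
  incidence <- pk %>%
    left_join(select(regions, "region_idx", "region_id"), by = "region_idx") %>%
    group_by(.data$region_id, .data$trait) %>%
    summarise(best_neglog10p = max(.data$best_neglog10p), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "trait",
                       values_from = "best_neglog10p")
  regions <- regions %>%
    select("region_id", "chrom", "start", "end", "n_traits", "traits",
           "ratio_only")
  list(regions = regions, incidence = incidence)
}
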