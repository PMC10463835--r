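#' Assign gene-region haplotypes
#'
#' Groups accessions by their identical dosage string over the region's
#' SNPs (haplotypes here are unphased SNP-genotype combinations, the
#' natural object in a selfing crop with minimal heterozygosity). Complete
#' accessions define the groups; groups reaching `min_freq` of all
#' accessions are major and labelled Hap-1, Hap-2, ... by descending count
#' (count ties broken by dosage string). Accessions with missing calls are
#' assigned to a major haplotype only when their non-missing sites match
#' exactly one major string; everything else is pooled as `"minor"`.
#'
#' @param gm A [genotype_matrix()] restricted to the gene span (see
#'   [subset_genotypes()]).
#' @param min_freq Major-haplotype frequency cutoff (inclusive), default
#'   0.05.
#' @return Object of class `hap_assign`: list with `assignment` (tibble:
#'   `accession`, `haplotype`), `haplotypes` (tibble: `haplotype`,
#'   `dosage_string`, `n`), `coverage` (share of accessions in major
#'   haplotypes), `snp_ids`.
#' @export
assign_haplotypes <- function(gm, min_freq = 0.05) {
  d <- gm$dosages
  poly <- apply(d, 2, function(x) {
    x <- x[!is.na(x)]
    length(unique(x)) > 1
  })
  if (!any(poly)) abort("region contains no polymorphic SNPs")
  d <- d[, poly, drop = FALSE]
  n <- nrow(d)
  complete <- rowSums(is.na(d)) == 0
  strings <- apply(d, 1, paste, collapse = ",")
  counts <- sort(table(strings[complete]), decreasing = TRUE)
  counts <- counts[order(-counts, names(counts))]
  major <- counts[counts / n >= min_freq]
  hap_labels <- if (length(major) > 0) {
    setNames(paste0("Hap-", seq_along(major)), names(major))
  } else {
    character()
  }

  assignment <- rep("minor", n)
  hit <- complete & strings %in% names(major)
  assignment[hit] <- hap_labels[strings[hit]]
  # incomplete accessions: unique compatible major haplotype or minor
  major_mat <- do.call(rbind, lapply(names(major), function(s) {
    as.numeric(strsplit(s, ",")[[1]])
  }))
  for (i in which(!complete)) {
    obs <- d[i, ]
    known <- !is.na(obs)
    if (!any(known) || length(major) == 0) next
    ok <- apply(major_mat, 1, function(h) all(h[known] == obs[known]))
    if (sum(ok) == 1) assignment[i] <- hap_labels[which(ok)]
  }

  tab <- tibble(
    haplotype = unname(hap_labels),
    dosage_string = names(major),
    n = as.integer(table(factor(assignment,
                                levels = unname(hap_labels)))[unname(hap_labels)])
  )
  structure(list(
    assignment = tibble(accession = rownames(d), haplotype = assignment),
    haplotypes = tab,
    coverage = mean(assignment != "minor"),
    snp_ids = colnames(d)
  ), class = "hap_assign")
}

#' @export
print.hap_assign <- function(x, ...) {
  cat(sprintf(
    "<hap_assign> %d major haplotype(s) over %d SNPs; coverage %.2f%%\n",
    nrow(x$haplotypes), length(x$snp_ids), 100 * x$coverage
  ))
  invisible(x)
}

#' Major-haplotype coverage from counts
#'
#' Share of accessions carried by the major haplotypes, as a percentage.
#'
#' @param counts Per-haplotype accession counts.
#' @param n_total Total number of accessions.
#' @return Percentage in \[0, 100\].
#' @export
haplotype_coverage <- function(counts, n_total) {
  100 * sum(counts) / n_total
}

#' Per-haplotype trait effects
#'
#' For each trait: haplotype means of the accession BLUEs, each haplotype's
#' difference from a reference haplotype both as a percentage
#' (`(mean - mean_ref) / mean_ref * 100`) and in absolute units, and LSD
#' letters from [lsd_groups()]. Haplotypes with fewer than `min_n`
#' accessions are tabulated but excluded from the significance test.
#'
#' @param assign A [assign_haplotypes()] result.
#' @param blues Wide BLUE table ([blue_table()]): `accession` + trait
#'   columns.
#' @param traits Trait columns to analyse.
#' @param reference Reference haplotype label, default `"Hap-1"`.
#' @param min_n Minimum group size for testing, default 3.
#' @param alpha LSD significance level.
#' @param include_minor Include the pooled "minor" class, default FALSE.
#' @return Tibble (`trait`, `haplotype`, `n`, `mean`, `pct_vs_ref`,
#'   `abs_vs_ref`, `letters`).
#' @export
haplotype_trait_effects <- function(assign, blues, traits,
                                    reference = "Hap-1", min_n = 3,
                                    alpha = 0.05, include_minor = FALSE) {
  joined <- assign$assignment %>%
    inner_join(blues, by = "accession")
  if (!include_minor) joined <- filter(joined, .data$haplotype != "minor")
  sizes <- count(joined, .data$haplotype)
  testable <- sizes$haplotype[sizes$n >= min_n]
  if (length(testable) < 2) abort("need >= 2 haplotypes with enough accessions")
  if (!reference %in% sizes$haplotype) abort("reference haplotype absent")

  purrr::map_dfr(traits, function(tr) {
    vals <- joined[[tr]]
    ok <- !is.na(vals)
    lsd <- lsd_groups(vals[ok & joined$haplotype %in% testable],
                      joined$haplotype[ok & joined$haplotype %in% testable],
                      alpha = alpha)
    stats_tbl <- joined[ok, ] %>%
      group_by(.data$haplotype) %>%
      summarise(n = n(), mean = mean(.data[[tr]]), .groups = "drop")
    ref_mean <- stats_tbl$mean[stats_tbl$haplotype == reference]
    stats_tbl %>%
      mutate(
        trait = tr,
        pct_vs_ref = (.data$mean - ref_mean) / ref_mean * 100,
        abs_vs_ref = .data$mean - ref_mean,
        letters = lsd$letters[match(.data$haplotype, lsd$group)]
      ) %>%
      select("trait", "haplotype", "n", "mean", "pct_vs_ref", "abs_vs_ref",
             "letters")
  })
}

#' Haplotype frequencies by region or release decade
#'
#' Counts and percentages of each haplotype within groups defined by
#' geographic region or by release decade (one bin up to 1970, then
#' ten-year bins to 2020). Accessions missing from the metadata fall into
#' an `"unknown"` group. Percentages within each group sum to 100.
#'
#' @param assign A [assign_haplotypes()] result.
#' @param metadata Tibble with `accession` and `region` / `release_year`
#'   (see [simulate_metadata()]).
#' @param group_by `"region"` or `"decade"`.
#' @return Tibble (`group`, `haplotype`, `n`, `pct`).
#' @export
haplotype_frequencies <- function(assign, metadata,
                                  group_by = c("region", "decade")) {
  group_by <- match.arg(group_by)
  meta <- metadata
  if (group_by == "decade" && !"decade" %in% names(meta)) {
    meta <- mutate(meta, decade = decade_bin(.data$release_year))
  }
  joined <- assign$assignment %>%
    left_join(meta, by = "accession") %>%
    mutate(group = dplyr::coalesce(.data[[group_by]], "unknown"))
  joined %>%
    count(.data$group, .data$haplotype, name = "n") %>%
    group_by(.data$group) %>%
    mutate(pct = 100 * .data$n / sum(.data$n)) %>%
    ungroup()
}
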