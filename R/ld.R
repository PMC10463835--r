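#' Pairwise LD between two SNPs
#'
#' Squared Pearson correlation of the unphased dosage vectors over jointly
#' non-missing accessions (the genotypic r-squared of Plink/PopLDdecay on
#' unphased data). Symmetric in allele labelling: replacing a column `x` by
#' `2 - x` leaves r-squared unchanged.
#'
#' @param gm A [genotype_matrix()].
#' @param snp_a,snp_b SNP ids.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(gm, snp_a, snp_b) {
  x <- gm$dosages[, snp_a]
  y <- gm$dosages[, snp_b]
  ok <- !is.na(x) & !is.na(y)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    abort("SNP monomorphic among jointly non-missing accessions; r2 undefined")
  }
  cor(x[ok], y[ok])^2
}

# r^2 matrix with pairwise-complete observations; monomorphic columns give NA
ld_matrix <- function(dos) {
  suppressWarnings(cor(dos, use = "pairwise.complete.obs"))^2
}

#' LD decay summary
#'
#' Bins all intra-chromosomal SNP pairs within `max_dist` by physical
#' distance and reports mean r-squared per bin, the maximum of the binned
#' curve, the half-maximum decay distance (midpoint of the first bin whose
#' mean r-squared falls to or below half the maximum), and the distance at
#' which the curve crosses r-squared = 0.50 (linear interpolation between
#' adjacent bins, `NA` when never crossed). Both conventions are reported
#' because both are in common use.
#'
#' @param gm A [genotype_matrix()].
#' @param max_dist Largest pair distance considered (bp).
#' @param bin_width Distance bin width (bp).
#' @param chroms Chromosomes to use; default all.
#' @return Object of class `ld_decay`: list with `curve` (tibble:
#'   `bin_start`, `bin_end`, `bin_mid`, `mean_r2`, `n_pairs`), `max_r2`,
#'   `half_max_dist`, `dist_r2_50`.
#' @export
ld_decay <- function(gm, max_dist = 5e6, bin_width = 1e5,
                     chroms = unique(gm$variants$chrom)) {
  pairs <- purrr::map_dfr(chroms, function(ch) {
    idx <- which(gm$variants$chrom == ch)
    if (length(idx) < 2) return(tibble())
    pos <- gm$variants$pos[idx]
    r2 <- ld_matrix(gm$dosages[, idx, drop = FALSE])
    ut <- which(upper.tri(r2), arr.ind = TRUE)
    dist <- abs(pos[ut[, 1]] - pos[ut[, 2]])
    keep <- dist <= max_dist & !is.na(r2[ut])
    tibble(dist = dist[keep], r2 = r2[ut][keep])
  })
  if (nrow(pairs) == 0) {
    abort("fewer than 2 usable SNPs on every chromosome")
  }
  curve <- pairs %>%
    mutate(bin = pmin(.data$dist %/% bin_width,
                      max_dist %/% bin_width - 1)) %>%
    group_by(.data$bin) %>%
    summarise(mean_r2 = mean(.data$r2), n_pairs = n(), .groups = "drop") %>%
    mutate(bin_start = .data$bin * bin_width,
           bin_end = (.data$bin + 1) * bin_width,
           bin_mid = .data$bin_start + bin_width / 2) %>%
    arrange(.data$bin) %>%
    select("bin_start", "bin_end", "bin_mid", "mean_r2", "n_pairs")
  max_r2 <- max(curve$mean_r2)
  below <- which(curve$mean_r2 <= max_r2 / 2)
  half_max_dist <- if (length(below) > 0) curve$bin_mid[below[1]] else NA_real_
  dist_r2_50 <- cross_distance(curve$bin_mid, curve$mean_r2, 0.5)
  structure(list(curve = curve, max_r2 = max_r2,
                 half_max_dist = half_max_dist, dist_r2_50 = dist_r2_50),
            class = "ld_decay")
}

# first downward crossing of `level`, linearly interpolated
cross_distance <- function(x, y, level) {
  if (y[1] <= level) return(x[1])
  for (i in seq_len(length(y) - 1)) {
    if (y[i] > level && y[i + 1] <= level) {
      return(x[i] + (x[i + 1] - x[i]) * (y[i] - level) / (y[i] - y[i + 1]))
    }
  }
  NA_real_
}

#' @export
print.ld_decay <- function(x, ...) {
  cat(sprintf(
    "<ld_decay> max mean r2 = %.3f; half-max distance = %s; r2=0.50 at %s\n",
    x$max_r2, format(x$half_max_dist, big.mark = ","),
    format(x$dist_r2_50, big.mark = ",")
  ))
  invisible(x)
}

#' Greedy sliding-window LD pruning
#'
#' Counts approximately independent markers the way Plink's
#' `--indep-pairwise`-style pruning does: starting from the first kept SNP
#' of each chromosome, all kept SNPs within `window_bp` of it form a
#' window; for every pair in the window with r-squared above `r2_max` the
#' later-positioned SNP is removed; the window start then advances by
#' `step` kept SNPs. Sweeps repeat until no SNP is removed, so no surviving
#' pair within any visited window exceeds `r2_max`.
#'
#' @param gm A [genotype_matrix()].
#' @param window_bp Window span in bp (default 50,000).
#' @param step Start-index advance in SNPs (default 5).
#' @param r2_max Pruning threshold (default 0.2).
#' @return List with `kept_ids`, `n_independent`, `n_input`.
#' @export
ld_prune <- function(gm, window_bp = 5e4, step = 5, r2_max = 0.2) {
  kept_all <- character()
  for (ch in unique(gm$variants$chrom)) {
    idx <- which(gm$variants$chrom == ch)
    pos <- gm$variants$pos[idx]
    ids <- gm$variants$id[idx]
    dos <- gm$dosages[, idx, drop = FALSE]
    keep <- rep(TRUE, length(idx))
    repeat {
      removed <- FALSE
      kidx <- which(keep)
      s <- 1
      while (s <= length(kidx)) {
        i0 <- kidx[s]
        win <- kidx[pos[kidx] >= pos[i0] & pos[kidx] <= pos[i0] + window_bp]
        if (length(win) > 1) {
          r2 <- ld_matrix(dos[, win, drop = FALSE])
          for (a in seq_len(length(win) - 1)) {
            if (!keep[win[a]]) next
            for (b in (a + 1):length(win)) {
              if (!keep[win[b]]) next
              if (!is.na(r2[a, b]) && r2[a, b] > r2_max) {
                keep[win[b]] <- FALSE
                removed <- TRUE
              }
            }
          }
        }
        kidx <- which(keep)
        s <- s + step
      }
      if (!removed) break
    }
    kept_all <- c(kept_all, ids[keep])
  }
  list(kept_ids = kept_all, n_independent = length(kept_all),
       n_input = ncol(gm$dosages))
}
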