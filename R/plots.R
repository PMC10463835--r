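#' Manhattan plot of an association scan
#'
#' @param object An [association_scan()] tibble (or several row-bound).
#' @param thresholds Optional [threshold_set()]; draws the working and
#'   Bonferroni lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.assoc_scan <- function(object, thresholds = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$pos / 1e6, y = .data$neglog10p,
                                    colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7, na.rm = TRUE) +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    p <- p +
      ggplot2::geom_hline(yintercept = thresholds$working_neglog10p,
                          linetype = "dashed") +
      ggplot2::geom_hline(yintercept = thresholds$bonferroni$neglog10p,
                          linetype = "dotted")
  }
  p
}

#' LD-decay curve plot
#'
#' @param object An [ld_decay()] result.
#' @param ... Unused.
#' @return A ggplot with the half-max distance marked.
#' @export
autoplot.ld_decay <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve,
                       ggplot2::aes(x = .data$bin_mid / 1e6,
                                    y = .data$mean_r2)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "distance (Mb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
  if (!is.na(object$half_max_dist)) {
    p <- p + ggplot2::geom_vline(xintercept = object$half_max_dist / 1e6,
                                 linetype = "dashed")
  }
  p
}

#' PCA scatter plot
#'
#' @param object A [pca_genotypes()] result.
#' @param colour_by Optional vector (e.g. subpopulation or region) matching
#'   the accession order.
#' @param ... Unused.
#' @return A ggplot of PC1 vs PC2 with variance fractions in the labels.
#' @export
autoplot.geno_pca <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  if (!is.null(colour_by)) df$group <- factor(colour_by)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_frac[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_frac[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(colour_by)) {
    p + ggplot2::geom_point(alpha = 0.8)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.8)
  }
}

#' Haplotype frequency bar plot
#'
#' @param freq A [haplotype_frequencies()] tibble.
#' @return A stacked percentage bar chart per group.
#' @export
plot_haplotype_frequencies <- function(freq) {
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$group, y = .data$pct,
                                     fill = .data$haplotype)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "frequency (%)") +
    ggplot2::theme_minimal()
}
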