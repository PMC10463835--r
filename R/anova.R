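#' Two-way variance components by expected mean squares
#'
#' Fits the two-way genotype x year model with replicates to one trait and
#' extracts variance components by the method of moments:
#' `var_e = MS_error`, `var_GxE = (MS_GxY - MS_error) / r`,
#' `var_G = (MS_G - MS_GxY) / (r * y)`, with negative estimates clamped to
#' zero and flagged. For random year/interaction effects the genotype and
#' year strata are tested against the interaction mean square, the
#' interaction against the error. Balanced designs use a closed-form
#' sums-of-squares path; unbalanced (but still crossed) designs fall back
#' to sequential [stats::aov()] sums of squares.
#'
#' @param obs Long tibble (`accession`, `year`, `rep`, `value`) for one
#'   trait; a `trait` column, if present, must be constant.
#' @param r Replicate count used in the moment equations; defaults to the
#'   mean number of replicates per genotype x year cell.
#' @return Object of class `variance_components`: list with `var_G`,
#'   `var_GxE`, `var_e`, `clamped`, `r`, `n_years`, `n_geno`, and an
#'   `anova` tibble (term, df, sumsq, meansq, statistic, p.value).
#' @export
anova_components <- function(obs, r = NULL) {
  if ("trait" %in% names(obs) && dplyr::n_distinct(obs$trait) > 1) {
    abort("anova_components expects observations for a single trait")
  }
  obs <- filter(obs, !is.na(.data$value))
  ng <- dplyr::n_distinct(obs$accession)
  ny <- dplyr::n_distinct(obs$year)
  cell <- obs %>% count(.data$accession, .data$year)
  if (ng < 2 || ny < 2 || all(cell$n < 2)) {
    abort("need >= 2 genotypes, >= 2 years and >= 2 replicates")
  }
  balanced <- dplyr::n_distinct(cell$n) == 1 && nrow(cell) == ng * ny
  if (is.null(r)) r <- mean(cell$n)

  if (balanced) {
    tab <- balanced_ss(obs, ng, ny, cell$n[1])
  } else {
    fit <- aov(value ~ factor(accession) + factor(year) +
                 factor(accession):factor(year), data = obs)
    s <- summary(fit)[[1]]
    term <- trimws(rownames(s))
    term <- c("genotype", "year", "genotype:year",
              "residual")[match(term, c("factor(accession)", "factor(year)",
                                        "factor(accession):factor(year)",
                                        "Residuals"))]
    tab <- tibble(term = term, df = s$Df, sumsq = s$`Sum Sq`,
                  meansq = s$`Mean Sq`)
  }
  ms <- setNames(tab$meansq, tab$term)
  df <- setNames(tab$df, tab$term)
  tab$statistic <- c(ms["genotype"] / ms["genotype:year"],
                     ms["year"] / ms["genotype:year"],
                     ms["genotype:year"] / ms["residual"], NA)
  denom_df <- c(df["genotype:year"], df["genotype:year"], df["residual"], NA)
  tab$p.value <- pf(tab$statistic, tab$df, denom_df, lower.tail = FALSE)

  var_e <- unname(ms["residual"])
  var_gxe <- unname((ms["genotype:year"] - ms["residual"]) / r)
  var_g <- unname((ms["genotype"] - ms["genotype:year"]) / (r * ny))
  clamped <- c(var_G = var_g < 0, var_GxE = var_gxe < 0)
  structure(list(
    var_G = max(var_g, 0), var_GxE = max(var_gxe, 0), var_e = var_e,
    clamped = clamped, r = r, n_years = ny, n_geno = ng, anova = tab
  ), class = "variance_components")
}

balanced_ss <- function(obs, ng, ny, r) {
  gmean <- mean(obs$value)
  mi <- obs %>% group_by(.data$accession) %>%
    summarise(m = mean(.data$value), .groups = "drop")
  mj <- obs %>% group_by(.data$year) %>%
    summarise(m = mean(.data$value), .groups = "drop")
  mij <- obs %>% group_by(.data$accession, .data$year) %>%
    summarise(m = mean(.data$value), .groups = "drop") %>%
    left_join(mi, by = "accession", suffix = c("", "_i")) %>%
    left_join(mj, by = "year", suffix = c("", "_j"))
  ss_g <- ny * r * sum((mi$m - gmean)^2)
  ss_y <- ng * r * sum((mj$m - gmean)^2)
  ss_gy <- r * sum((mij$m - mij$m_i - mij$m_j + gmean)^2)
  resid <- obs %>%
    left_join(select(mij, "accession", "year", "m"),
              by = c("accession", "year"))
  ss_e <- sum((resid$value - resid$m)^2)
  tibble(
    term = c("genotype", "year", "genotype:year", "residual"),
    df = c(ng - 1, ny - 1, (ng - 1) * (ny - 1), ng * ny * (r - 1)),
    sumsq = c(ss_g, ss_y, ss_gy, ss_e)
  ) %>%
    mutate(meansq = .data$sumsq / .data$df)
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> var_G = %.4g, var_GxE = %.4g, var_e = %.4g%s\n",
    x$var_G, x$var_GxE, x$var_e,
    if (any(x$clamped)) " (clamped)" else ""
  ))
  invisible(x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' `H2 = var_G / (var_G + var_GxE / y + var_e / (y * r))`, the two-year,
#' five-replicate form generalized to `y` years and `r` replicates.
#'
#' @param vc A [anova_components()] result, or a list with `var_G`,
#'   `var_GxE`, `var_e`.
#' @param n_years Number of years `y`.
#' @param r Number of replicates per year.
#' @return Heritability in \[0, 1\].
#' @export
heritability <- function(vc, n_years = vc$n_years, r = vc$r) {
  if (vc$var_G < 0 || vc$var_GxE < 0 || vc$var_e < 0) {
    abort("variance components must be >= 0")
  }
  denom <- vc$var_G + vc$var_GxE / n_years + vc$var_e / (n_years * r)
  if (denom == 0) abort("all variance components are zero; H2 undefined")
  vc$var_G / denom
}
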