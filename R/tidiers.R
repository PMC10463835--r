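#' Tidy a variance-components fit
#'
#' @param x A [anova_components()] result.
#' @param ... Unused.
#' @return The ANOVA table as a tibble (term, df, sumsq, meansq, statistic,
#'   p.value).
#' @export
tidy.variance_components <- function(x, ...) x$anova

#' One-row summary of a variance-components fit
#'
#' @param x A [anova_components()] result.
#' @param ... Unused.
#' @return Tibble with `var_G`, `var_GxE`, `var_e`, `H2`, `clamped`.
#' @export
glance.variance_components <- function(x, ...) {
  tibble(
    var_G = x$var_G, var_GxE = x$var_GxE, var_e = x$var_e,
    H2 = heritability(x), clamped = any(x$clamped),
    n_geno = x$n_geno, n_years = x$n_years, r = x$r
  )
}

#' Tidy a null mixed-model fit
#'
#' @param x A [fit_null_mlm()] result.
#' @param ... Unused.
#' @return Tibble of covariate fixed-effect estimates.
#' @export
tidy.mlm_null <- function(x, ...) {
  nm <- colnames(x$S)
  if (is.null(nm)) nm <- paste0("S", seq_along(x$beta))
  tibble(term = nm, estimate = x$beta)
}

#' One-row summary of a null mixed-model fit
#'
#' @param x A [fit_null_mlm()] result.
#' @param ... Unused.
#' @return Tibble with `lambda`, `sigma2_g`, `sigma2_e`, `loglik`.
#' @export
glance.mlm_null <- function(x, ...) {
  tibble(lambda = x$lambda, sigma2_g = x$sigma2_g, sigma2_e = x$sigma2_e,
         loglik = x$loglik)
}

#' Tidy a haplotype assignment
#'
#' @param x A [assign_haplotypes()] result.
#' @param ... Unused.
#' @return The accession-to-haplotype tibble.
#' @export
tidy.hap_assign <- function(x, ...) x$assignment

#' One-row summary of a haplotype assignment
#'
#' @param x A [assign_haplotypes()] result.
#' @param ... Unused.
#' @return Tibble with `n_major`, `coverage_pct`, `n_snps`.
#' @export
glance.hap_assign <- function(x, ...) {
  tibble(n_major = nrow(x$haplotypes), coverage_pct = 100 * x$coverage,
         n_snps = length(x$snp_ids))
}
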