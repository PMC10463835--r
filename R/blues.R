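#' Best linear unbiased estimates per genotype
#'
#' Fits value = genotype (fixed) + year (random) + genotype x year (random)
#' and returns the genotype fixed-effect estimates. For a fully balanced,
#' complete design the BLUE of each genotype equals its raw mean across
#' years and replicates, and that closed form is used directly; unbalanced
#' designs are fitted by REML via [lme4::lmer()]. Setting
#' `genotype_random = TRUE` instead treats genotype as random and returns
#' BLUPs (conditional means), for users who want the literal all-random
#' reading of the two-way model.
#'
#' @param obs Long tibble (`accession`, `year`, `rep`, `value`) for one
#'   trait.
#' @param genotype_random Return BLUPs from an all-random model instead of
#'   BLUEs. Default `FALSE`.
#' @return Tibble (`accession`, `blue`) with attribute `"method"` one of
#'   `"balanced_mean"`, `"reml"`, `"blup"`.
#' @export
compute_blues <- function(obs, genotype_random = FALSE) {
  obs <- filter(obs, !is.na(.data$value))
  if ("trait" %in% names(obs) && dplyr::n_distinct(obs$trait) > 1) {
    abort("compute_blues expects observations for a single trait")
  }
  ng <- dplyr::n_distinct(obs$accession)
  ny <- dplyr::n_distinct(obs$year)
  if (ng < 2 || ny < 2) abort("need >= 2 genotypes and >= 2 years")
  cell <- obs %>% count(.data$accession, .data$year)
  balanced <- dplyr::n_distinct(cell$n) == 1 && nrow(cell) == ng * ny

  if (genotype_random) {
    fit <- lme4::lmer(
      value ~ 1 + (1 | accession) + (1 | year) + (1 | accession:year),
      data = obs, REML = TRUE
    )
    re <- lme4::ranef(fit)$accession
    out <- tibble(accession = rownames(re),
                  blue = lme4::fixef(fit)[["(Intercept)"]] + re[["(Intercept)"]])
    attr(out, "method") <- "blup"
    return(arrange(out, .data$accession))
  }

  if (balanced) {
    out <- obs %>%
      group_by(.data$accession) %>%
      summarise(blue = mean(.data$value), .groups = "drop") %>%
      arrange(.data$accession)
    attr(out, "method") <- "balanced_mean"
    return(out)
  }

  obs <- mutate(obs, accession = factor(.data$accession),
                year = factor(.data$year))
  fit <- lme4::lmer(value ~ 0 + accession + (1 | year) + (1 | accession:year),
                    data = obs, REML = TRUE)
  fe <- lme4::fixef(fit)
  out <- tibble(
    accession = sub("^accession", "", names(fe)),
    blue = unname(fe)
  ) %>% arrange(.data$accession)
  attr(out, "method") <- "reml"
  attr(out, "fit") <- fit
  out
}

#' BLUE table for many traits
#'
#' Maps [compute_blues()] over every trait and widens to accession x trait.
#'
#' @param obs Long tibble (`accession`, `trait`, `year`, `rep`, `value`).
#' @param traits Traits to keep; defaults to all present.
#' @return Tibble with `accession` plus one column per trait.
#' @export
blue_table <- function(obs, traits = unique(obs$trait)) {
  purrr::map_dfr(traits, function(tr) {
    compute_blues(filter(obs, .data$trait == tr)) %>%
      mutate(trait = tr)
  }) %>%
    tidyr::pivot_wider(id_cols = "accession", names_from = "trait",
                       values_from = "blue")
}
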