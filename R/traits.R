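#' Definitions of the 15 derived assimilate-partitioning traits
#'
#' Each derived trait is a ratio of two measured spike-component traits,
#' optionally scaled (thousand kernel weight multiplies grain weight /
#' grain number by 1000). Ten ratios describe the entire spike, five the
#' central spikelet.
#'
#' @return Tibble (`trait`, `kind`, `numerator`, `denominator`, `scale`).
#' @export
trait_definitions <- function() {
  measured <- measured_trait_catalog() %>%
    select(trait = "trait") %>%
    mutate(kind = "measured", numerator = NA_character_,
           denominator = NA_character_, scale = NA_real_)
  ratios <- tibble::tribble(
    ~trait, ~numerator, ~denominator, ~scale,
    # entire spike
    "tkw",                       "grain_weight",          "grain_number",          1000,
    "grain_number_per_chaff",    "grain_number",          "chaff_weight",          1,
    "grain_weight_per_chaff",    "grain_weight",          "chaff_weight",          1,
    "grain_weight_per_spike",    "grain_weight",          "spike_weight",          1,
    "grain_weight_per_rachis",   "grain_weight",          "rachis_weight",         1,
    "spikelet_density",          "spikelet_number",       "spike_length",          1,
    "chaff_per_spike_weight",    "chaff_weight",          "spike_weight",          1,
    "awn_per_spike_weight",      "awn_weight",            "spike_weight",          1,
    "awn_per_grain_weight",      "awn_weight",            "grain_weight",          1,
    "awn_per_chaff_weight",      "awn_weight",            "chaff_weight",          1,
    # central spikelet
    "grain_weight_per_chaff_spikelet", "grain_weight_spikelet", "chaff_weight_spikelet", 1,
    "tkw_spikelet",              "grain_weight_spikelet", "grain_number_spikelet", 1000,
    "fruiting_efficiency_spikelet", "grain_number_spikelet", "chaff_weight_spikelet", 1,
    "grain_weight_per_spikelet_weight", "grain_weight_spikelet", "spikelet_weight",   1,
    "chaff_per_spikelet_weight", "chaff_weight_spikelet", "spikelet_weight",       1
  ) %>%
    mutate(kind = "ratio") %>%
    select("trait", "kind", "numerator", "denominator", "scale")
  bind_rows(measured, ratios)
}

#' Derive ratio traits per replicate
#'
#' Widens the measured observations per accession x year x replicate,
#' computes every ratio trait on that replicate level (never on averages),
#' and returns the long table of measured plus derived traits. Records
#' whose denominator is zero, negative or missing are dropped; the dropped
#' count is attached as attribute `"dropped"`.
#'
#' @param obs Long tibble (`accession`, `trait`, `year`, `rep`, `value`)
#'   containing the measured traits.
#' @param defs Trait definitions, default [trait_definitions()].
#' @return Long tibble with measured and derived traits.
#' @export
derive_traits <- function(obs, defs = trait_definitions()) {
  ratio_defs <- filter(defs, .data$kind == "ratio")
  wide <- obs %>%
    filter(.data$trait %in% c(ratio_defs$numerator, ratio_defs$denominator)) %>%
    tidyr::pivot_wider(id_cols = c("accession", "year", "rep"),
                       names_from = "trait", values_from = "value")
  dropped <- 0L
  skipped <- character()
  derived <- purrr::pmap_dfr(ratio_defs, function(trait, kind, numerator,
                                                  denominator, scale) {
    if (!all(c(numerator, denominator) %in% names(wide))) {
      skipped <<- c(skipped, trait)
      return(tibble())
    }
    num <- wide[[numerator]]
    den <- wide[[denominator]]
    ok <- !is.na(num) & !is.na(den) & den > 0
    dropped <<- dropped + sum(!ok)
    tibble(
      accession = wide$accession[ok], trait = trait,
      year = wide$year[ok], rep = wide$rep[ok],
      value = scale * num[ok] / den[ok]
    )
  })
  if (length(skipped) > 0) {
    warn(sprintf("%d ratio trait(s) skipped for missing components: %s",
                 length(skipped), paste(skipped, collapse = ", ")))
  }
  out <- bind_rows(obs, derived) %>%
    arrange(.data$trait, .data$accession, .data$year, .data$rep)
  attr(out, "dropped") <- dropped
  attr(out, "skipped_traits") <- skipped
  out
}
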