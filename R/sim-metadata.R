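#' Simulate accession metadata
#'
#' Assigns each accession a geographic region (seven continental labels:
#' AF, AS, EU, MEA, NA., OA, SA) and a release year/decade. Each
#' subpopulation has a "home" region that an accession inherits with
#' probability `region_coupling` (otherwise a uniform random region), so
#' haplotype-geography analyses have signal; release years span 1900-2020.
#'
#' @param cfg A [sim_config()].
#' @param subpop Optional integer vector of subpopulation assignments named
#'   by accession (taken from [simulate_genotypes()]'s attribute); generated
#'   round-robin when absent.
#' @return Tibble (`accession`, `subpop`, `region`, `release_year`, `decade`).
#' @export
simulate_metadata <- function(cfg, subpop = NULL) {
  validate_sim_config(cfg)
  regions <- c("AF", "AS", "EU", "MEA", "NA.", "OA", "SA")
  n <- cfg$n_accessions
  acc <- sprintf("ACC%03d", seq_len(n))
  if (is.null(subpop)) {
    subpop <- rep(seq_len(cfg$n_subpops), length.out = n)
    names(subpop) <- acc
  } else {
    acc <- names(subpop)
  }
  withr::with_seed(cfg$seed + 3000L, {
    home <- regions[(seq_len(cfg$n_subpops) - 1L) %% length(regions) + 1L]
    use_home <- runif(n) < cfg$region_coupling
    region <- ifelse(use_home, home[subpop],
                     sample(regions, n, replace = TRUE))
    year <- sample(1900:2020, n, replace = TRUE)
    tibble(
      accession = acc, subpop = unname(subpop), region = region,
      release_year = year, decade = decade_bin(year)
    )
  })
}

#' Bin release years the way breeding-history summaries do
#'
#' Years up to 1970 fall in one "<=1970" bin, later years in 10-year bins
#' (1971-1980, ..., 2011-2020).
#'
#' @param year Integer vector of release years.
#' @return Character vector of bin labels.
#' @export
decade_bin <- function(year) {
  ifelse(year <= 1970, "<=1970",
         paste0(pmin((year - 1971) %/% 10, 4) * 10 + 1971, "-",
                pmin((year - 1971) %/% 10, 4) * 10 + 1980))
}

#' Simulate a gene annotation track
#'
#' Tiles genes along each simulated chromosome (default one gene per 200 kb,
#' 3 kb span, alternating strand) so candidate-gene windowing has targets.
#'
#' @param cfg A [sim_config()].
#' @param gene_every_bp Spacing between gene starts.
#' @param gene_span_bp Gene length.
#' @return Tibble (`gene_id`, `chrom`, `start`, `end`, `strand`), 1-based
#'   inclusive coordinates.
#' @export
simulate_annotation <- function(cfg, gene_every_bp = 2e5, gene_span_bp = 3e3) {
  validate_sim_config(cfg)
  purrr::map_dfr(seq_len(cfg$n_chroms), function(ci) {
    starts <- seq(1e4, cfg$chrom_length_bp - gene_span_bp, by = gene_every_bp)
    tibble(
      gene_id = sprintf("Gene%dG%04d", ci, seq_along(starts)),
      chrom = paste0("chr", ci),
      start = as.integer(starts),
      end = as.integer(starts + gene_span_bp - 1),
      strand = rep_len(c("+", "-"), length(starts))
    )
  })
}

#' Simulate stage-wise gene expression
#'
#' Draws FPKM values for six spike-development stages (ZM1-ZM6) per gene
#' from a log-normal, with a configurable fraction of silent genes so the
#' expression filter separates candidates.
#'
#' @param annotation Tibble from [simulate_annotation()].
#' @param cfg A [sim_config()].
#' @param silent_frac Fraction of genes with FPKM ~ 0 in all stages.
#' @return Tibble (`gene_id`, `stage`, `fpkm`).
#' @export
simulate_expression <- function(annotation, cfg, silent_frac = 0.4) {
  stages <- paste0("ZM", 1:6)
  withr::with_seed(cfg$seed + 4000L, {
    ng <- nrow(annotation)
    silent <- runif(ng) < silent_frac
    purrr::map_dfr(seq_len(ng), function(i) {
      fpkm <- if (silent[i]) {
        round(runif(6, 0, 0.2), 3)
      } else {
        round(stats::rlnorm(6, meanlog = 1.5, sdlog = 1), 3)
      }
      tibble(gene_id = annotation$gene_id[i], stage = stages, fpkm = fpkm)
    })
  })
}
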