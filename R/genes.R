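#' Candidate genes around a peak's lead SNP
#'
#' Lists genes whose span intersects the window
#' `[lead - window_bp, lead + window_bp]` (1-based inclusive). Distance to
#' the lead SNP is 0 when the lead lies inside the gene span, otherwise the
#' bp gap to the nearest gene edge. A gene passes the expression filter
#' when its FPKM reaches `fpkm_min` in any of the six spike-development
#' stages (ZM1-ZM6). Genes are ranked passes-expression first, then by
#' distance.
#'
#' @param peak One row of a [merge_and_call_peaks()] tibble (or any list
#'   with `chrom` and `lead_pos`).
#' @param annotation Gene tibble (`gene_id`, `chrom`, `start`, `end`), e.g.
#'   from [read_gff3_genes()] or [simulate_annotation()].
#' @param expression Long tibble (`gene_id`, `stage`, `fpkm`).
#' @param window_bp Half-window around the lead SNP, default 500 kb.
#' @param fpkm_min Expression threshold, default 1.
#' @return Tibble (`gene_id`, `chrom`, `start`, `end`, `distance`,
#'   `max_fpkm`, `passes_expression`, `rank`).
#' @export
candidate_genes <- function(peak, annotation, expression,
                            window_bp = 5e5, fpkm_min = 1) {
  chrom <- peak$chrom[1]
  lead <- peak$lead_pos[1]
  ann <- filter(annotation, .data$chrom == .env$chrom)
  if (nrow(ann) == 0) {
    warn(sprintf("annotation has no genes on %s", chrom))
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), distance = numeric(),
                  max_fpkm = numeric(), passes_expression = logical(),
                  rank = integer()))
  }
  hit <- ann$end >= lead - window_bp & ann$start <= lead + window_bp
  ann <- ann[hit, , drop = FALSE]
  expr <- expression %>%
    group_by(.data$gene_id) %>%
    summarise(max_fpkm = max(.data$fpkm), .groups = "drop")
  ann %>%
    mutate(distance = dplyr::case_when(
      lead >= .data$start & lead <= .data$end ~ 0,
      lead < .data$start ~ .data$start - lead,
      TRUE ~ lead - .data$end
    )) %>%
    left_join(expr, by = "gene_id") %>%
    mutate(max_fpkm = dplyr::coalesce(.data$max_fpkm, 0),
           passes_expression = .data$max_fpkm >= fpkm_min) %>%
    arrange(desc(.data$passes_expression), .data$distance) %>%
    mutate(rank = row_number()) %>%
    select("gene_id", "chrom", "start", "end", "distance", "max_fpkm",
           "passes_expression", "rank")
}
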