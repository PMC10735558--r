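#' Assemble marker-trait associations into QTL
#'
#' Chains same-chromosome MTAs whose physical distance is strictly below
#' `merge_distance` (single linkage: the chain is transitive, so a QTL span
#' can exceed the merge distance) into QTL, numbered along the genome as
#' `Q.<prefix>.<NN>`. A QTL is flagged `consistent` when its member MTAs
#' include a combined-analysis context AND more than one individual
#' environment. When a second panel's QTL table is supplied, a QTL is
#' flagged `true_positive` if its span overlaps a same-chromosome QTL of
#' that panel (closed intervals, 1-based physical bp). The representative
#' marker is the member with the highest LOD, ties broken by highest
#' r-squared, then lowest position.
#'
#' @param mtas MTA tibble (from [call_mtas()]), with `marker_id`,
#'   `chromosome`, `position`, `trait`, `context`, `lod`, `r2_marker`.
#' @param merge_distance maximum gap (bp) for two MTAs to share a QTL;
#'   conventionally twice the panel's LD decay distance.
#' @param combined_contexts character vector of context labels that count as
#'   combined analyses; defaults to contexts starting with `"combined"`.
#' @param prefix identifier prefix (default `"SIM"`).
#' @param other_panel_qtl optional QTL tibble from another panel (columns
#'   `chromosome`, `span_start`, `span_end`) used for the `true_positive`
#'   flag.
#' @return QTL tibble: `qtl_id`, `chromosome`, `span_start`, `span_end`,
#'   `n_mtas`, `traits`, `contexts`, `consistent`, `true_positive`,
#'   `representative_marker`, `member_mtas` (list column).
#' @export
assemble_qtl <- function(mtas, merge_distance,
                         combined_contexts = NULL, prefix = "SIM",
                         other_panel_qtl = NULL) {
  mtas <- as_tibble(mtas)
  if (nrow(mtas) == 0) {
    return(tibble(qtl_id = character(), chromosome = character(),
                  span_start = numeric(), span_end = numeric(),
                  n_mtas = integer(), traits = character(),
                  contexts = character(), consistent = logical(),
                  true_positive = logical(),
                  representative_marker = character(),
                  member_mtas = list()))
  }
  is_combined <- if (is.null(combined_contexts))
    function(ctx) grepl("^combined", ctx)
  else function(ctx) ctx %in% combined_contexts

  mtas <- arrange(mtas, .data$chromosome, .data$position, .data$marker_id)
  qtl_rows <- mtas |>
    group_by(.data$chromosome) |>
    mutate(cluster = cumsum(c(1, diff(.data$position) >= merge_distance))) |>
    ungroup() |>
    group_by(.data$chromosome, .data$cluster) |>
    summarise(
      span_start = min(.data$position),
      span_end = max(.data$position),
      n_mtas = dplyr::n(),
      traits = paste(sort(unique(.data$trait)), collapse = ","),
      contexts = paste(sort(unique(.data$context)), collapse = ","),
      consistent = any(is_combined(.data$context)) &&
        dplyr::n_distinct(.data$context[!is_combined(.data$context)]) > 1,
      representative_marker = {
        o <- order(-.data$lod, -.data$r2_marker, .data$position)
        .data$marker_id[o[1]]
      },
      member_mtas = list(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    ) |>
    arrange(.data$chromosome, .data$span_start) |>
    mutate(qtl_id = sprintf("Q.%s.%02d", prefix, row_number())) |>
    select(-"cluster")

  qtl_rows$true_positive <- FALSE
  if (!is.null(other_panel_qtl)) {
    other <- as_tibble(other_panel_qtl)
    qtl_rows$true_positive <- purrr::pmap_lgl(
      qtl_rows[c("chromosome", "span_start", "span_end")],
      function(chromosome, span_start, span_end) {
        o <- other[other$chromosome == chromosome, ]
        any(o$span_start <= span_end & o$span_end >= span_start)
      })
  }
  qtl_rows |>
    select("qtl_id", "chromosome", "span_start", "span_end", "n_mtas",
           "traits", "contexts", "consistent", "true_positive",
           "representative_marker", "member_mtas")
}
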