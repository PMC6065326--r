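#' Hypergeometric pathway over-representation
#'
#' Tests, for every pathway in the universe annotation, whether the query
#' target set contains more of its members than expected under random
#' sampling from the universe (one-sided hypergeometric upper tail: the
#' probability of an overlap at least as large as observed). P-values are
#' corrected with the Benjamini-Hochberg step-up procedure across all tested
#' pathways; a pathway passes when its FDR is below `fdr_threshold`.
#'
#' @param query_targets Character vector of target identifiers; must be a
#'   subset of the universe annotation's targets.
#' @param universe_annotation Annotation table defining pathway membership
#'   in the background (see [annotation_table()]).
#' @param universe_size Number of targets in the background. Defaults to the
#'   number of distinct targets in `universe_annotation`.
#' @param fdr_threshold FDR cutoff, default 0.01.
#' @return A tibble of class `tpt_enrichment`, one row per pathway with
#'   columns `pathway_id`, `overlap_count`, `pathway_size`, `query_size`,
#'   `universe_size`, `p_value`, `fdr`, `passed`, sorted by ascending
#'   p-value with ties broken by pathway id.
#' @export
#' @examples
#' ann <- annotation_table(tibble::tibble(
#'   target_id = c("T1", "T2", "T3", "T4"),
#'   pathway_id = c("P1", "P1", "P2", "P2")))
#' enrich_pathways(c("T1", "T2"), ann, fdr_threshold = 0.5)
enrich_pathways <- function(query_targets, universe_annotation,
                            universe_size = NULL, fdr_threshold = 0.01) {
  query_targets <- unique(trimws(query_targets))
  query_targets <- query_targets[query_targets != ""]
  if (length(query_targets) == 0) {
    abort("query target set is empty", class = "tpt_empty_input_error")
  }
  universe_targets <- unique(universe_annotation$target_id)
  stray <- setdiff(query_targets, universe_targets)
  if (length(stray) > 0) {
    abort(paste0("query targets absent from the universe annotation: ",
                 paste(head(stray, 5), collapse = ", ")),
          class = "tpt_usage_error")
  }
  if (is.null(universe_size)) universe_size <- length(universe_targets)
  if (universe_size < length(universe_targets)) {
    abort("universe_size is smaller than the number of annotated targets",
          class = "tpt_usage_error")
  }
  q <- length(query_targets)

  per_pathway <- universe_annotation |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(
      pathway_size = dplyr::n_distinct(.data$target_id),
      overlap_count = sum(unique(.data$target_id) %in% query_targets),
      .groups = "drop")
  empty <- per_pathway$pathway_size == 0
  if (any(empty)) {
    warn(paste0("excluding ", sum(empty), " pathway(s) with no members"),
         class = "tpt_empty_pathway_warning")
    per_pathway <- per_pathway[!empty, , drop = FALSE]
  }

  res <- per_pathway |>
    dplyr::mutate(
      query_size = q,
      universe_size = as.integer(universe_size),
      p_value = phyper(.data$overlap_count - 1, .data$pathway_size,
                       universe_size - .data$pathway_size, q,
                       lower.tail = FALSE),
      fdr = p.adjust(.data$p_value, method = "BH"),
      passed = .data$fdr < fdr_threshold) |>
    dplyr::arrange(.data$p_value, .data$pathway_id) |>
    dplyr::select("pathway_id", "overlap_count", "pathway_size",
                  "query_size", "universe_size", "p_value", "fdr", "passed")
  class(res) <- c("tpt_enrichment", class(res))
  attr(res, "fdr_threshold") <- fdr_threshold
  res
}

#' Restrict an annotation to enriched pathways
#'
#' Keeps exactly the (target, pathway) pairs whose pathway passed the
#' over-representation filter; targets left with no retained pathway drop
#' out of the table entirely.
#'
#' @param annotation An annotation table.
#' @param result A `tpt_enrichment` result computed from `annotation`.
#' @return The filtered annotation tibble.
#' @export
filter_annotation <- function(annotation, result) {
  keep <- result$pathway_id[result$passed]
  dplyr::filter(annotation, .data$pathway_id %in% keep)
}
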