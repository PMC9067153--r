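#' Genes excluded by the dual-region methylation rule
#'
#' A gene with both a promoter and a body call in the same comparison is
#' excluded when the methylation change is large in either region
#' (default rule: `max(|meth_diff_summary|) > threshold`, strict). The
#' alternative reading — exclusion when the two regions' changes differ
#' from each other by more than the threshold — is available as
#' `rule = "between-region"`.
#'
#' @param region_calls Region calls from [call_region_dm()] for one
#'   comparison.
#' @param threshold Percentage-point threshold (default 20, strict `>`).
#' @param rule `"either-region"` (default) or `"between-region"`.
#' @return Tibble `gene_id`, `promoter_diff`, `body_diff`, `rule_value` for
#'   the excluded genes (the side table of dual-region genes).
#' @export
exclude_dual <- function(region_calls, threshold = 20,
                         rule = c("either-region", "between-region")) {
  rule <- match.arg(rule)
  both <- tidyr::pivot_wider(
    dplyr::select(region_calls, "gene_id", "region", "meth_diff_summary"),
    names_from = "region", values_from = "meth_diff_summary"
  )
  for (col in c("promoter", "body"))
    if (!col %in% names(both)) both[[col]] <- NA_real_
  both <- dplyr::filter(both, !is.na(.data$promoter), !is.na(.data$body))
  val <- if (rule == "either-region") {
    pmax(abs(both$promoter), abs(both$body))
  } else {
    abs(both$promoter - both$body)
  }
  tibble::tibble(gene_id = both$gene_id, promoter_diff = both$promoter,
                 body_diff = both$body, rule_value = val) |>
    dplyr::filter(.data$rule_value > threshold) |>
    dplyr::arrange(.data$gene_id)
}

#' Integrate differential expression with region methylation calls
#'
#' Joins one comparison's filtered differential expression table with its
#' gene-region methylation calls and keeps the direction-concordant
#' pairings only: promoter methylation anti-correlated with expression
#' (hypo with up, hyper with down) and gene-body methylation positively
#' correlated (hyper with up, hypo with down). Genes failing the
#' dual-region rule ([exclude_dual()]) are removed; region calls with
#' mixed-sign member DMCs are skipped by default. A gene can be emitted
#' once per qualifying (region, direction) pairing, so a gene kept by both
#' its promoter and its body yields two rows.
#'
#' @param de Filtered DE table ([filter_de()]) or a full
#'   [differential_expression()] result (rows with `ns` are ignored).
#' @param region_calls Region calls from [call_region_dm()], same ordered
#'   comparison.
#' @param comparison Length-2 character vector `c(group_a, group_b)`.
#' @param dual_threshold Threshold of the dual-region rule.
#' @param dual_rule Rule variant, see [exclude_dual()].
#' @param drop_discordant Skip region calls flagged discordant.
#' @return Tibble `gene_id`, `group_a`, `group_b`, `expr_direction`,
#'   `region`, `meth_direction`, `mode`, `log2fc`, `meth_diff_summary`,
#'   ordered by (gene_id, region). The dual-region side table is attached
#'   as attribute `"excluded"`.
#' @export
integrate_comparison <- function(de, region_calls, comparison,
                                 dual_threshold = 20,
                                 dual_rule = c("either-region",
                                               "between-region"),
                                 drop_discordant = TRUE) {
  dual_rule <- match.arg(dual_rule)
  stopifnot(length(comparison) == 2)
  if ("direction" %in% names(de)) {
    de <- dplyr::filter(de, .data$direction %in% c("up", "down"))
  } else {
    abort("`de` must carry a direction column.")
  }
  excluded <- exclude_dual(region_calls, dual_threshold, dual_rule)
  calls <- dplyr::filter(region_calls,
                         !.data$gene_id %in% excluded$gene_id)
  if (drop_discordant) calls <- dplyr::filter(calls, !.data$discordant)

  out <- dplyr::inner_join(
    dplyr::select(de, "gene_id", expr_direction = "direction", "log2fc"),
    dplyr::select(calls, "gene_id", "region",
                  meth_direction = "direction", "meth_diff_summary"),
    by = "gene_id", relationship = "many-to-many"
  ) |>
    dplyr::filter(
      (.data$region == "promoter" & .data$meth_direction == "hypo" &
         .data$expr_direction == "up") |
        (.data$region == "promoter" & .data$meth_direction == "hyper" &
           .data$expr_direction == "down") |
        (.data$region == "body" & .data$meth_direction == "hyper" &
           .data$expr_direction == "up") |
        (.data$region == "body" & .data$meth_direction == "hypo" &
           .data$expr_direction == "down")
    ) |>
    dplyr::mutate(
      group_a = comparison[1], group_b = comparison[2],
      mode = paste(.data$region, .data$meth_direction,
                   .data$expr_direction, sep = "-")
    ) |>
    dplyr::select("gene_id", "group_a", "group_b", "expr_direction",
                  "region", "meth_direction", "mode", "log2fc",
                  "meth_diff_summary") |>
    dplyr::arrange(.data$gene_id, .data$region)
  attr(out, "excluded") <- excluded
  out
}
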