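#' Run the full methylome-transcriptome integration across the model
#'
#' Convenience wrapper chaining every stage for a set of pairwise
#' comparisons: differential expression, per-CpG differential methylation,
#' region calling, direction-consistent integration, and (when all needed
#' comparisons are present) the three progression signatures.
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param cpg Long CpG tibble (see [read_cpg_tables()]).
#' @param samples Sample sheet (`sample`, `group`) covering both assays.
#' @param annotation Annotation tibble.
#' @param comparisons List of `c(group_a, group_b)` pairs; defaults to all
#'   ordered pairs of the four progression lines that the signature
#'   definitions use, plus the premalignant/nonmetastatic contrast.
#' @param lfc_min,alpha DE thresholds (defaults 2 and 0.01).
#' @param engine DE engine ([differential_expression()]).
#' @param min_cov,q_max,diff_min DMC thresholds (defaults 10, 0.01, 25).
#' @param min_cpgs,flank Region-call parameters (defaults 3 and 500).
#' @param dual_threshold Dual-region exclusion threshold (default 20).
#' @param signatures Derive the three signatures (default TRUE).
#' @return List with `de` (named list of DE tibbles), `dmcs`,
#'   `region_calls`, `integrated` (one bound tibble), `excluded` (dual-
#'   region side tables) and, if requested, `signatures` (named list).
#' @export
run_progression_analysis <- function(counts, cpg, samples, annotation,
                                     comparisons = NULL, lfc_min = 2,
                                     alpha = 0.01,
                                     engine = c("moderated", "welch"),
                                     min_cov = 10, q_max = 0.01,
                                     diff_min = 25, min_cpgs = 3,
                                     flank = 500, dual_threshold = 20,
                                     signatures = TRUE) {
  engine <- match.arg(engine)
  lines <- default_lines()
  if (is.null(comparisons)) {
    comparisons <- list(
      c(lines[["parent"]], lines[["premalignant"]]),
      c(lines[["parent"]], lines[["nonmetastatic"]]),
      c(lines[["parent"]], lines[["metastatic"]]),
      c(lines[["premalignant"]], lines[["nonmetastatic"]]),
      c(lines[["premalignant"]], lines[["metastatic"]]),
      c(lines[["nonmetastatic"]], lines[["metastatic"]])
    )
  }
  names(comparisons) <- purrr::map_chr(comparisons,
                                       ~ comparison_label(.x[1], .x[2]))
  de <- purrr::map(comparisons, function(cp) {
    differential_expression(counts, samples, cp[1], cp[2], engine = engine,
                            lfc_min = lfc_min, alpha = alpha)
  })
  dmcs <- purrr::map(comparisons, function(cp) {
    call_dmcs(cpg, samples, cp[1], cp[2], min_cov = min_cov, q_max = q_max,
              diff_min = diff_min)
  })
  region_calls <- purrr::map(dmcs, call_region_dm, annotation = annotation,
                             min_cpgs = min_cpgs, flank = flank)
  integrated <- purrr::imap(comparisons, function(cp, lab) {
    integrate_comparison(filter_de(de[[lab]], lfc_min, alpha),
                         region_calls[[lab]], cp,
                         dual_threshold = dual_threshold)
  })
  excluded <- purrr::map(integrated, attr, "excluded")
  all_integrated <- dplyr::bind_rows(integrated)
  out <- list(de = de, dmcs = dmcs, region_calls = region_calls,
              integrated = all_integrated, excluded = excluded)
  if (signatures) {
    out$signatures <- list(
      malignancy = signature_malignancy(all_integrated),
      EMT = signature_emt(all_integrated),
      metastasis = signature_metastasis(all_integrated)
    )
  }
  out
}
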