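#' Map CpG sites to promoter and gene-body regions
#'
#' Promoters span TSS +/- `flank` (inclusive at both ends); gene bodies run
#' from TSS + `flank` + 1 to the transcription terminus, both in
#' transcription-oriented coordinates, so the boundary base TSS + `flank`
#' belongs to the promoter only and the two regions are disjoint per gene.
#' The strand of the *gene* orients the arithmetic; the strand of the CpG
#' is ignored, and opposite-strand CpG calls are never merged. A site may
#' map to regions of several overlapping genes (one output row each);
#' unassigned sites are dropped.
#'
#' @param sites Tibble with columns `chrom`, `pos` (1-based) and optionally
#'   `strand`.
#' @param annotation Annotation tibble (see [read_annotation()]).
#' @param flank Promoter half-width in bp.
#' @return Tibble: the input site columns plus `gene_id` and `region`
#'   (`promoter` or `body`).
#' @export
assign_regions <- function(sites, annotation, flank = 500) {
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  windows <- region_windows(annotation, flank)
  keep <- windows$start <= windows$end    # short genes may lack a body
  windows <- windows[keep, ]

  q <- GenomicRanges::GRanges(sites$chrom,
                              IRanges::IRanges(sites$pos, width = 1))
  s <- GenomicRanges::GRanges(windows$chrom,
                              IRanges::IRanges(windows$start, windows$end))
  hits <- GenomicRanges::findOverlaps(q, s, ignore.strand = TRUE)
  out <- dplyr::bind_cols(
    sites[S4Vectors::queryHits(hits), , drop = FALSE],
    tibble::tibble(
      gene_id = windows$gene_id[S4Vectors::subjectHits(hits)],
      region = windows$region[S4Vectors::subjectHits(hits)]
    )
  )
  dplyr::arrange(out, .data$chrom, .data$pos, .data$gene_id, .data$region)
}

# promoter/body windows in absolute chromosome coordinates
region_windows <- function(annotation, flank) {
  ann <- annotation
  body_start <- ifelse(ann$strand == "+", ann$tss + flank + 1, ann$tx_start)
  body_end <- ifelse(ann$strand == "+", ann$tx_end, ann$tss - flank - 1)
  tibble::tibble(
    gene_id = rep(ann$gene_id, 2),
    chrom = rep(ann$chrom, 2),
    region = rep(c("promoter", "body"), each = nrow(ann)),
    start = pmax(c(ann$tss - flank, body_start), 1L),
    end = c(ann$tss + flank, body_end)
  )
}

#' Lift site-level differential methylation to gene-region calls
#'
#' Groups differentially methylated CpGs (rows of `dmcs` with
#' `is_dmc == TRUE`) by gene and region and emits a region call when at
#' least `min_cpgs` DMCs fall inside. The summarized methylation change is
#' the arithmetic mean of the member DMC differences; regions whose member
#' DMCs disagree in sign are flagged `discordant`. With
#' `count = "tested"`, the `min_cpgs` requirement applies to tested CpGs
#' instead (any DMC then triggers a call).
#'
#' @param dmcs Per-CpG results from [call_dmcs()] (all tested sites).
#' @param annotation Annotation tibble.
#' @param min_cpgs Minimum CpG count for a call (default 3).
#' @param flank Promoter half-width in bp.
#' @param count Whether `min_cpgs` counts DMCs (default) or tested CpGs.
#' @return Tibble with `gene_id`, `region`, `n_dmc`, `n_cpg_tested`,
#'   `meth_diff_summary`, `direction` (`hyper`/`hypo`), `discordant`.
#' @export
call_region_dm <- function(dmcs, annotation, min_cpgs = 3, flank = 500,
                           count = c("dmc", "tested")) {
  count <- match.arg(count)
  assigned <- assign_regions(dmcs, annotation, flank = flank)
  tested <- dplyr::count(assigned, .data$gene_id, .data$region,
                         name = "n_cpg_tested")
  calls <- dplyr::filter(assigned, .data$is_dmc) |>
    dplyr::group_by(.data$gene_id, .data$region) |>
    dplyr::summarise(
      n_dmc = dplyr::n(),
      meth_diff_summary = mean(.data$meth_diff),
      discordant = length(unique(sign(.data$meth_diff))) > 1,
      .groups = "drop"
    ) |>
    dplyr::left_join(tested, by = c("gene_id", "region")) |>
    dplyr::mutate(direction = dplyr::if_else(.data$meth_diff_summary >= 0,
                                     "hyper", "hypo"))
  calls <- if (count == "dmc") {
    dplyr::filter(calls, .data$n_dmc >= min_cpgs)
  } else {
    dplyr::filter(calls, .data$n_cpg_tested >= min_cpgs)
  }
  dplyr::select(calls, "gene_id", "region", "n_dmc", "n_cpg_tested",
                "meth_diff_summary", "direction", "discordant") |>
    dplyr::arrange(.data$gene_id, .data$region)
}
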