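#' Kaplan-Meier plot for a log-rank result
#'
#' Step curves of the product-limit estimates of both groups, annotated
#' with the log-rank p-value.
#'
#' @param object An `epi_logrank` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.epi_logrank <- function(object, ...) {
  curves <- dplyr::bind_rows(
    tibble::tibble(group = object$groups$group, time = 0, survival = 1),
    dplyr::select(object$curves, "group", "time", "survival")
  )
  ggplot2::ggplot(curves,
                  ggplot2::aes(.data$time, .data$survival,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "time (years)", y = "survival probability",
      subtitle = paste0("log-rank p = ", signif(object$p, 3))
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a pairwise differential expression result
#'
#' @param de Result of [differential_expression()].
#' @param lfc_min,alpha Thresholds drawn as guides.
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, lfc_min = 2, alpha = 0.01) {
  ggplot2::ggplot(de, ggplot2::aes(.data$log2fc, -log10(.data$p_adj),
                                   colour = .data$direction)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::geom_vline(xintercept = c(-lfc_min, lfc_min),
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2980b9", ns = "grey70")
    ) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Integration mode counts per comparison
#'
#' Bar chart of how many genes each comparison yields in each of the four
#' concordant methylation-expression modes.
#'
#' @param integrated Combined [integrate_comparison()] output (one or more
#'   comparisons).
#' @return A ggplot object.
#' @export
plot_integration <- function(integrated) {
  d <- dplyr::count(as_integrated_tbl(integrated),
                    comparison = comparison_label(.data$group_a,
                                                  .data$group_b),
                    .data$mode)
  ggplot2::ggplot(d, ggplot2::aes(.data$comparison, .data$n,
                                  fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "genes") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Methylation change versus expression change
#'
#' Scatter of the summarized region methylation difference against the
#' expression log2 fold change for every integrated gene, split by region
#' (promoter pairings fall in the discordant-sign quadrants, body pairings
#' in the concordant ones).
#'
#' @param integrated Combined [integrate_comparison()] output.
#' @return A ggplot object.
#' @export
plot_methylation_expression <- function(integrated) {
  d <- as_integrated_tbl(integrated)
  ggplot2::ggplot(d, ggplot2::aes(.data$meth_diff_summary / 100,
                                  .data$log2fc / 10,
                                  colour = .data$region)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "methylation difference / 100",
                  y = "expression log2FC / 10") +
    ggplot2::theme_minimal()
}
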