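#' Log2 counts-per-million
#'
#' `log2((count + pseudocount) / library_size * 1e6)` with library size the
#' column sum of raw counts. The pseudocount keeps zero counts finite.
#'
#' @param counts Tibble `gene_id` + sample columns.
#' @param pseudocount Added to every count before the log.
#' @return Tibble of the same shape with log2-CPM values.
#' @export
log2_cpm <- function(counts, pseudocount = 0.5) {
  mat <- as.matrix(dplyr::select(counts, -"gene_id"))
  lib <- colSums(mat)
  if (any(lib == 0)) abort("sample with zero total counts.")
  lcpm <- log2(t((t(mat) + pseudocount) / lib) * 1e6)
  dplyr::bind_cols(tibble::tibble(gene_id = counts$gene_id),
                   tibble::as_tibble(lcpm))
}

#' Pairwise differential expression between two groups
#'
#' Tests every gene between `group_a` and `group_b` on log2-CPM values;
#' `log2fc` is mean(B) - mean(A). Two test engines are available:
#'
#' * `"moderated"` (default): an empirical-Bayes moderated t-test. The
#'   gene-wise pooled variances are squeezed toward a common prior
#'   estimated by the method of moments on `log(s^2)`, and the t statistic
#'   is referred to a t distribution with `d0 + dfres` degrees of freedom.
#'   With triplicates the residual df alone (4) is far too small to detect
#'   even 8-fold changes at stringent FDR; borrowing strength across genes
#'   is what makes the design workable.
#' * `"welch"`: a plain two-sided Welch t-test per gene.
#'
#' P-values are Benjamini-Hochberg adjusted across all genes in the
#' comparison. `direction` is `up`/`down` only when both
#' `|log2fc| >= lfc_min` and `p_adj <= alpha` hold (thresholds inclusive),
#' otherwise `ns`.
#'
#' @param counts Tibble `gene_id` + sample columns.
#' @param samples Sample sheet (`sample`, `group`).
#' @param group_a,group_b Group labels; fold changes are B relative to A.
#' @param pseudocount Pseudocount for log2-CPM.
#' @param engine Test engine, see Details.
#' @param lfc_min Minimum absolute log2 fold change (default 2).
#' @param alpha Maximum BH-adjusted p (default 0.01).
#' @param allow_single Allow single-replicate groups; p-values are then NA
#'   and every direction is `ns`.
#' @return Tibble `gene_id`, `log2fc`, `p_raw`, `p_adj`, `direction`.
#' @export
differential_expression <- function(counts, samples, group_a, group_b,
                                    pseudocount = 0.5,
                                    engine = c("moderated", "welch"),
                                    lfc_min = 2, alpha = 0.01,
                                    allow_single = FALSE) {
  engine <- match.arg(engine)
  sa <- group_samples(samples, group_a)
  sb <- group_samples(samples, group_b)
  missing <- setdiff(c(sa, sb), names(counts))
  if (length(missing) > 0)
    abort(paste0("samples absent from count matrix: ",
                 paste(missing, collapse = ", ")))
  if ((length(sa) < 2 || length(sb) < 2) && !allow_single)
    abort("need >= 2 replicates per group (or allow_single = TRUE).")

  lcpm <- log2_cpm(counts[c("gene_id", sa, sb)], pseudocount)
  la <- as.matrix(lcpm[sa])
  lb <- as.matrix(lcpm[sb])
  lfc <- rowMeans(lb) - rowMeans(la)

  if (length(sa) < 2 || length(sb) < 2) {
    p <- rep(NA_real_, length(lfc))
  } else if (engine == "welch") {
    p <- welch_t(la, lb)
  } else {
    p <- moderated_t(la, lb)
  }
  p_adj <- p.adjust(p, method = "BH")
  tibble::tibble(
    gene_id = lcpm$gene_id, log2fc = lfc, p_raw = p, p_adj = p_adj,
    direction = dplyr::case_when(
      is.na(p_adj) ~ "ns",
      abs(lfc) >= lfc_min & p_adj <= alpha & lfc > 0 ~ "up",
      abs(lfc) >= lfc_min & p_adj <= alpha & lfc < 0 ~ "down",
      TRUE ~ "ns"
    )
  )
}

welch_t <- function(la, lb) {
  na <- ncol(la); nb <- ncol(lb)
  va <- rowSums((la - rowMeans(la))^2) / (na - 1)
  vb <- rowSums((lb - rowMeans(lb))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (rowMeans(lb) - rowMeans(la)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * pt(-abs(tt), df)
}

# Empirical-Bayes moderated t on pooled two-sample variances. The prior
# (d0, s0^2) comes from the moments of z = log(s^2): under a scaled-F model
# var(z) = trigamma(dfres/2) + trigamma(d0/2), and E[z] identifies s0^2
# after digamma bias correction. d0 = Inf (variances essentially common)
# collapses every gene to the bias-corrected global variance.
moderated_t <- function(la, lb) {
  na <- ncol(la); nb <- ncol(lb)
  dfres <- na + nb - 2
  ss <- rowSums((la - rowMeans(la))^2) + rowSums((lb - rowMeans(lb))^2)
  s2 <- pmax(ss / dfres, 1e-12)
  z <- log(s2)
  vz <- var(z) - trigamma(dfres / 2)
  if (is.finite(vz) && vz > 1e-8) {
    d0 <- 2 * inv_trigamma(vz)
    s02 <- exp(mean(z) - digamma(dfres / 2) + log(dfres / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s02 + dfres * s2) / (d0 + dfres)
    dft <- d0 + dfres
  } else {
    s02 <- exp(mean(z) - digamma(dfres / 2) + log(dfres / 2))
    s2_post <- rep(s02, length(s2))
    dft <- Inf
  }
  tt <- (rowMeans(lb) - rowMeans(la)) / sqrt(s2_post * (1 / na + 1 / nb))
  2 * pt(-abs(tt), dft)
}

inv_trigamma <- function(x) {
  # Newton iteration on trigamma(y) = x (Smyth 2004, appendix)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif) < 1e-8 * y) break
  }
  y
}

#' Filter a differential expression table at the effect/significance cut
#'
#' Keeps genes with `|log2fc| >= lfc_min` and `p_adj <= alpha` (both
#' inclusive) and returns their direction of change.
#'
#' @param de Result of [differential_expression()].
#' @param lfc_min,alpha Thresholds (defaults 2 and 0.01).
#' @return Tibble `gene_id`, `log2fc`, `p_adj`, `direction` (`up`/`down`).
#' @export
filter_de <- function(de, lfc_min = 2, alpha = 0.01) {
  dplyr::filter(de, !is.na(.data$p_adj), abs(.data$log2fc) >= lfc_min,
                .data$p_adj <= alpha) |>
    dplyr::mutate(direction = dplyr::if_else(.data$log2fc > 0, "up", "down")) |>
    dplyr::select("gene_id", "log2fc", "p_adj", "direction")
}
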