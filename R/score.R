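#' Z-transform a feature-by-patient matrix
#'
#' Centers and scales every feature across patients to mean 0 and sample
#' variance 1 (n-1 denominator). Zero-variance features are dropped with a
#' warning rather than propagating NaN.
#'
#' @param mat Tibble with a `feature` column and one numeric column per
#'   patient (>= 2 patients).
#' @return Tibble of the same shape (minus dropped features).
#' @export
zscore_matrix <- function(mat) {
  if (!"feature" %in% names(mat)) abort("matrix needs a feature column.")
  x <- as.matrix(dplyr::select(mat, -"feature"))
  if (ncol(x) < 2) abort("z-transformation needs >= 2 patients.")
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  keep <- s > 0
  if (!all(keep))
    warn(paste0(sum(!keep), " zero-variance feature(s) dropped."))
  z <- (x[keep, , drop = FALSE] - mu[keep]) / s[keep]
  dplyr::bind_cols(tibble::tibble(feature = mat$feature[keep]),
                   tibble::as_tibble(z))
}

#' Per-patient signature scores
#'
#' Averages z-transformed expression over the signature's members:
#' `up_score` over upregulated genes, `down_score` over downregulated
#' genes, and `combined_score` the mean with weight +1 for up and -1 for
#' down members, i.e. `(sum z_up - sum z_down) / (n_up + n_down)` over the
#' members present in the matrix. With one set empty the combined score
#' equals the other set's mean. Missing signature genes are reported via a
#' message; zero overlap is an error.
#'
#' @param z Z-scored matrix from [zscore_matrix()].
#' @param signature An `epi_signature` or tibble (`gene_id`, `direction`).
#' @return Tibble `patient_id`, `up_score`, `down_score`,
#'   `combined_score`, `signature`.
#' @export
signature_score <- function(z, signature) {
  sig <- as_signature_tbl(signature)
  name <- attr(signature, "name", exact = TRUE) %||% "signature"
  present <- dplyr::filter(sig, .data$gene_id %in% z$feature)
  if (nrow(present) == 0)
    abort(paste0("no gene of signature '", name,
                 "' is present in the matrix."))
  n_missing <- nrow(sig) - nrow(present)
  if (n_missing > 0)
    inform(paste0(n_missing, " gene(s) of signature '", name,
                  "' absent from the matrix."))
  x <- as.matrix(dplyr::select(z, -"feature"))
  rows <- match(present$gene_id, z$feature)
  up <- rows[present$direction == "up"]
  dn <- rows[present$direction == "down"]
  up_score <- if (length(up) > 0) unname(colMeans(x[up, , drop = FALSE]))
    else rep(NA_real_, ncol(x))
  down_score <- if (length(dn) > 0) unname(colMeans(x[dn, , drop = FALSE]))
    else rep(NA_real_, ncol(x))
  w <- c(rep(1, length(up)), rep(-1, length(dn)))
  combined <- unname(colSums(x[c(up, dn), , drop = FALSE] * w) /
                       (length(up) + length(dn)))
  tibble::tibble(patient_id = colnames(x), up_score = up_score,
                 down_score = down_score, combined_score = combined,
                 signature = name)
}

#' Dichotomize scores at the median
#'
#' Patients strictly above the median score are `high`; at or below,
#' `low`, so group sizes differ only by the count of median ties.
#'
#' @param scores Tibble with `patient_id` and a score column, or a named
#'   numeric vector.
#' @param score_col Name of the score column (default `combined_score`).
#' @return Tibble `patient_id`, `score`, `group` (`high`/`low`).
#' @export
dichotomize_median <- function(scores, score_col = "combined_score") {
  s <- extract_scores(scores, score_col)
  if (length(s) < 2) abort("need >= 2 patients.")
  if (max(s) == min(s)) abort("all scores identical: cannot dichotomize.")
  med <- median(s)
  tibble::tibble(patient_id = names(s), score = unname(s),
                 group = unname(ifelse(s > med, "high", "low")))
}

#' Stratify patients into outer quartiles
#'
#' Patients strictly below the `low_q` percentile form the `low` group and
#' those strictly above the `high_q` percentile the `high` group; the
#' middle is `excluded`. Percentiles use the linear-interpolation
#' convention of [stats::quantile()] type 7. Grouping is invariant under
#' any strictly increasing transform of the values.
#'
#' @param scores As in [dichotomize_median()] (>= 8 patients).
#' @param low_q,high_q Percentile bounds (defaults 0.25 and 0.75).
#' @param score_col Name of the score column.
#' @return Tibble `patient_id`, `score`, `group`
#'   (`low`/`high`/`excluded`).
#' @export
quartile_stratify <- function(scores, low_q = 0.25, high_q = 0.75,
                              score_col = "combined_score") {
  s <- extract_scores(scores, score_col)
  if (length(s) < 8) abort("need >= 8 patients for quartile stratification.")
  if (max(s) == min(s)) abort("all scores identical: cannot stratify.")
  qs <- quantile(s, c(low_q, high_q), type = 7, names = FALSE)
  grp <- dplyr::case_when(s < qs[1] ~ "low", s > qs[2] ~ "high",
                          TRUE ~ "excluded")
  if (sum(grp == "low") < 2 || sum(grp == "high") < 2)
    abort("fewer than 2 patients in an outer quartile group.")
  tibble::tibble(patient_id = names(s), score = unname(s), group = grp)
}

extract_scores <- function(scores, score_col) {
  if (is.data.frame(scores)) {
    if (!all(c("patient_id", score_col) %in% names(scores)))
      abort(paste0("scores need columns patient_id and ", score_col, "."))
    setNames(scores[[score_col]], scores$patient_id)
  } else if (is.numeric(scores) && !is.null(names(scores))) {
    scores
  } else {
    abort("scores must be a tibble or a named numeric vector.")
  }
}

#' Association between a score and a clinical covariate
#'
#' Spearman rank correlation (average ranks for ties) with a two-sided
#' asymptotic p-value.
#'
#' @param score,covariate Paired numeric vectors; pairs with missing
#'   values are dropped, at least 5 complete pairs required.
#' @return Tibble `rho`, `p`, `n`.
#' @export
covariate_association <- function(score, covariate) {
  stopifnot(length(score) == length(covariate))
  ok <- !is.na(score) & !is.na(covariate)
  score <- score[ok]; covariate <- covariate[ok]
  if (length(score) < 5) abort("need >= 5 complete pairs.")
  if (max(score) == min(score) || max(covariate) == min(covariate))
    abort("constant input: correlation undefined.")
  ct <- suppressWarnings(
    cor.test(score, covariate, method = "spearman", exact = FALSE)
  )
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value,
                 n = length(score))
}
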