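#' Tidy a Cox fit
#' @param x An `epi_cox` object.
#' @param ... Unused.
#' @return One row per model term with estimate, standard error, hazard
#'   ratio, 95% CI and Wald p-value.
#' @exportS3Method generics::tidy
tidy.epi_cox <- function(x, ...) {
  dplyr::rename(x$terms, std.error = "se", p.value = "p_wald",
                conf.low = "ci_low", conf.high = "ci_high")
}

#' @rdname tidy.epi_cox
#' @exportS3Method generics::glance
glance.epi_cox <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, logLik = x$loglik,
                 logLik_null = x$loglik0,
                 statistic_lr = 2 * (x$loglik - x$loglik0),
                 iterations = x$iter)
}

#' Tidy a log-rank test
#' @param x An `epi_logrank` object.
#' @param ... Unused.
#' @return A one-row tibble with the chi-squared statistic and p-value.
#' @exportS3Method generics::tidy
tidy.epi_logrank <- function(x, ...) {
  tibble::tibble(statistic = x$chi2, df = 1, p.value = x$p)
}

#' @rdname tidy.epi_logrank
#' @exportS3Method generics::glance
glance.epi_logrank <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, statistic = x$chi2,
                 p.value = x$p)
}

#' Tidy a signature
#' @param x An `epi_signature` object.
#' @param ... Unused.
#' @return The member tibble with the signature name as a column.
#' @exportS3Method generics::tidy
tidy.epi_signature <- function(x, ...) {
  dplyr::mutate(tibble::as_tibble(x), signature = attr(x, "name", exact = TRUE),
                .before = 1)
}

#' @rdname tidy.epi_signature
#' @exportS3Method generics::glance
glance.epi_signature <- function(x, ...) {
  tibble::tibble(signature = attr(x, "name", exact = TRUE), n_genes = nrow(x),
                 n_up = sum(x$direction == "up"),
                 n_down = sum(x$direction == "down"))
}
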