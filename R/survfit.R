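#' Kaplan-Meier curve table
#'
#' Product-limit survival estimate per group, one row per distinct
#' observed time (event or censoring).
#'
#' @param group Group label per patient.
#' @param time Follow-up time (> 0).
#' @param event Event indicator (1 = event, 0 = censored).
#' @return Tibble `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @export
km_curve <- function(group, time, event) {
  check_surv(time, event)
  purrr::map(split(seq_along(time), group), function(idx) {
    t <- time[idx]; e <- event[idx]
    ut <- sort(unique(t))
    n_risk <- purrr::map_int(ut, ~ sum(t >= .x))
    d <- purrr::map_int(ut, ~ sum(t == .x & e == 1))
    cns <- purrr::map_int(ut, ~ sum(t == .x & e == 0))
    tibble::tibble(time = ut, n_risk = n_risk, n_event = d, n_censor = cns,
                   survival = cumprod(1 - d / n_risk))
  }) |>
    dplyr::bind_rows(.id = "group")
}

#' Two-group log-rank test with Kaplan-Meier curves
#'
#' The classic log-rank statistic: over the pooled distinct event times,
#' `chi2 = (sum(O - E))^2 / sum(V)` with the expected events and
#' hypergeometric variance of group 1 at each risk set; p from a
#' chi-squared distribution with 1 df.
#'
#' @inheritParams km_curve
#' @return An `epi_logrank` object with elements `chi2`, `p`, `n`,
#'   `n_events`, `groups` (per-group sizes) and `curves`
#'   (the [km_curve()] table). Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
km_logrank <- function(group, time, event) {
  check_surv(time, event)
  group <- as.character(group)
  levs <- sort(unique(group))
  if (length(levs) != 2) abort("log-rank test needs exactly two groups.")
  if (min(table(factor(group, levs))) == 0) abort("empty group.")
  if (sum(event) == 0) abort("no events observed.")

  is1 <- group == levs[1]
  ut <- sort(unique(time[event == 1]))
  o <- e <- v <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at <- time >= ut[k]
    n <- sum(at); n1 <- sum(at & is1)
    d <- sum(time == ut[k] & event == 1)
    d1 <- sum(time == ut[k] & event == 1 & is1)
    o[k] <- d1
    e[k] <- d * n1 / n
    v[k] <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
  }
  sv <- sum(v)
  chi2 <- if (sv > 0) (sum(o) - sum(e))^2 / sv else 0
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  fgrp <- factor(group, levs)
  group_sizes <- tibble::tibble(
    group = levs,
    n = as.integer(table(fgrp)),
    n_events = as.integer(tapply(event, fgrp, sum))
  )
  structure(
    list(chi2 = chi2, p = p, n = length(time), n_events = sum(event),
         groups = group_sizes, curves = km_curve(group, time, event)),
    class = "epi_logrank"
  )
}

check_surv <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(is.na(time)) || any(time <= 0)) abort("time must be > 0.")
  if (!all(event %in% c(0, 1))) abort("event must be 0/1.")
}

#' @export
print.epi_logrank <- function(x, ...) {
  cat("Log-rank test: chi2 =", format(x$chi2, digits = 4),
      "(1 df), p =", format(x$p, digits = 4), "\n")
  cat("n =", x$n, ", events =", x$n_events, "\n")
  invisible(x)
}

#' Cox proportional hazards fit
#'
#' Maximizes the Cox partial likelihood by Newton-Raphson with the Efron
#' correction for tied event times. The first column of the design is the
#' covariate of interest; the reported hazard ratio, 95% confidence
#' interval and Wald p refer to it (all terms are available via
#' [tidy()]).
#'
#' @param x Numeric covariate of interest per patient (e.g. a signature
#'   score, or a 0/1 group indicator).
#' @param time,event Survival outcome as in [km_curve()].
#' @param extra Optional data frame / matrix of adjustment covariates.
#' @param max_iter,tol Newton-Raphson controls.
#' @return An `epi_cox` object: `terms` tibble (`term`, `estimate`, `se`,
#'   `hazard_ratio`, `ci_low`, `ci_high`, `p_wald`), `loglik`, `loglik0`,
#'   `n`, `n_events`, `iter`. Has [tidy()] and [glance()] methods.
#' @export
cox_fit <- function(x, time, event, extra = NULL, max_iter = 50,
                    tol = 1e-9) {
  check_surv(time, event)
  X <- cbind(score = x)
  if (!is.null(extra)) X <- cbind(X, as.matrix(extra))
  storage.mode(X) <- "double"
  if (nrow(X) != length(time)) abort("covariate length mismatch.")
  if (anyNA(X)) abort("missing values in covariates.")
  cons <- apply(X, 2, function(v) max(v) == min(v))
  if (any(cons))
    abort(paste0("constant covariate: ", colnames(X)[cons][1]))
  if (sum(event) < 10)
    warn("fewer than 10 events: estimates may be unstable.")

  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]
  X_s <- X[ord, , drop = FALSE]
  n <- length(t_s); p <- ncol(X_s)
  ut <- unique(t_s[e_s == 1])
  start <- match(ut, t_s)                      # first index of each risk set
  dsets <- lapply(ut, function(t) which(t_s == t & e_s == 1))

  beta <- rep(0, p)
  ll0 <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- drop(X_s %*% beta)
    w <- exp(eta)
    wX <- X_s * w
    # suffix sums: risk-set aggregates for every start index
    W0 <- rev(cumsum(rev(w)))
    W1 <- apply(wX, 2, function(col) rev(cumsum(rev(col))))
    ll <- 0; U <- rep(0, p); I <- matrix(0, p, p)
    for (k in seq_along(ut)) {
      D <- dsets[[k]]; d <- length(D)
      s0r <- W0[start[k]]
      s1r <- W1[start[k], ]
      s2r <- crossprod(X_s[start[k]:n, , drop = FALSE],
                       wX[start[k]:n, , drop = FALSE])
      s0d <- sum(w[D])
      s1d <- colSums(wX[D, , drop = FALSE])
      s2d <- crossprod(X_s[D, , drop = FALSE], wX[D, , drop = FALSE])
      ll <- ll + sum(eta[D])
      U <- U + colSums(X_s[D, , drop = FALSE])
      for (l in seq_len(d) - 1) {
        f <- l / d
        phi0 <- s0r - f * s0d
        phi1 <- s1r - f * s1d
        phi2 <- s2r - f * s2d
        ll <- ll - log(phi0)
        U <- U - phi1 / phi0
        I <- I + phi2 / phi0 - tcrossprod(phi1) / phi0^2
      }
    }
    if (iter == 1) ll0 <- ll
    step <- tryCatch(solve(I, U), error = function(e)
      abort("singular information matrix (collinear covariates?)."))
    beta_new <- beta + step
    if (any(abs(beta_new) > 15))
      abort("divergent fit: complete separation or monotone likelihood.")
    done <- max(abs(step)) < tol
    beta <- beta_new
    if (done) break
  }
  if (!done) abort(paste0("Newton-Raphson did not converge in ", max_iter,
                          " iterations (last step ", format(max(abs(step))),
                          ")."))
  se <- unname(sqrt(diag(solve(I))))
  beta <- unname(beta)
  zq <- qnorm(0.975)
  terms <- tibble::tibble(
    term = colnames(X_s), estimate = beta, se = se,
    hazard_ratio = exp(beta),
    ci_low = exp(beta - zq * se), ci_high = exp(beta + zq * se),
    p_wald = 2 * stats::pnorm(-abs(beta / se))
  )
  structure(
    list(terms = terms, loglik = ll, loglik0 = ll0, n = n,
         n_events = sum(e_s), iter = iter),
    class = "epi_cox"
  )
}

#' @export
print.epi_cox <- function(x, ...) {
  cat("Cox proportional hazards (Efron ties), n =", x$n, ", events =",
      x$n_events, "\n")
  print(x$terms)
  invisible(x)
}
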