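#' Per-CpG differential methylation test between two groups
#'
#' With at least two replicates in either group, a likelihood-ratio test of
#' the binomial logistic model `methylated/coverage ~ group` against the
#' intercept-only model (the group-wise MLEs are the coverage-pooled
#' proportions, so the statistic has a closed form). With one replicate per
#' group, a two-sided Fisher exact test on the pooled 2x2 table, computed
#' by exhaustive hypergeometric enumeration. The methylation difference is
#' always `100 * (pooled B proportion - pooled A proportion)`, in
#' percentage points.
#'
#' @param meth_a,cov_a Methylated and total read counts per replicate of
#'   group A (equal-length integer vectors).
#' @param meth_b,cov_b Same for group B.
#' @return List with `p_raw`, `meth_diff` and `method` (`"lrt"` or
#'   `"fisher"`).
#' @export
cpg_test <- function(meth_a, cov_a, meth_b, cov_b) {
  stopifnot(length(meth_a) == length(cov_a),
            length(meth_b) == length(cov_b))
  if (any(meth_a < 0 | meth_a > cov_a) || any(meth_b < 0 | meth_b > cov_b))
    abort("need 0 <= meth <= coverage in every sample.")
  ma <- sum(meth_a); ca <- sum(cov_a)
  mb <- sum(meth_b); cb <- sum(cov_b)
  if (ca == 0 || cb == 0) abort("zero total coverage in a group.")
  diff <- 100 * (mb / cb - ma / ca)
  if (length(meth_a) == 1 && length(meth_b) == 1) {
    p <- fisher_two_sided(ma, ca, mb, cb)
    list(p_raw = p, meth_diff = diff, method = "fisher")
  } else {
    p <- binom_lrt(ma, ca, mb, cb)
    list(p_raw = p, meth_diff = diff, method = "lrt")
  }
}

# vectorized closed-form LRT: methylated/coverage ~ group vs intercept-only
binom_lrt <- function(ma, ca, mb, cb) {
  ll <- function(m, n, p) {
    p <- pmin(pmax(p, 1e-300), 1 - 1e-16)
    m * log(p) + (n - m) * log1p(-p)
  }
  pa <- ma / ca; pb <- mb / cb; p0 <- (ma + mb) / (ca + cb)
  stat <- 2 * (ll(ma, ca, pa) + ll(mb, cb, pb) -
                 ll(ma, ca, p0) - ll(mb, cb, p0))
  pchisq(pmax(stat, 0), df = 1, lower.tail = FALSE)
}

# Two-sided Fisher exact p for the table (m1, c1-m1; m2, c2-m2) by
# enumeration: sum of hypergeometric probabilities of all tables with the
# same margins that are no more probable than the observed one (with the
# customary 1 + 1e-7 relative tolerance).
fisher_two_sided <- function(m1, c1, m2, c2) {
  k <- m1 + m2
  lo <- max(0, k - c2)
  hi <- min(k, c1)
  probs <- dhyper(lo:hi, c1, c2, k)
  obs <- dhyper(m1, c1, c2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Call differentially methylated cytosines between two groups
#'
#' Applies the per-sample coverage filter, tests every retained site with
#' [cpg_test()] (vectorized), adjusts p-values across all tested sites
#' (Benjamini-Hochberg by default) and flags DMCs at the inclusive
#' thresholds `q_value <= q_max` and `|meth_diff| >= diff_min`.
#' Sites where any sample of either group has coverage below `min_cov`
#' are excluded before testing.
#'
#' @param cpg Long CpG tibble (see [read_cpg_tables()]).
#' @param samples Sample sheet (`sample`, `group`).
#' @param group_a,group_b Group labels; differences are B minus A.
#' @param min_cov Per-sample minimum coverage (default 10).
#' @param q_max Maximum q-value for a DMC (default 0.01).
#' @param diff_min Minimum absolute methylation difference in percentage
#'   points (default 25).
#' @param qvalue_fun Function mapping raw p-values to q-values; defaults to
#'   Benjamini-Hochberg.
#' @return Tibble `chrom`, `pos`, `strand`, `meth_diff`, `p_raw`,
#'   `q_value`, `is_dmc`, one row per tested site.
#' @export
call_dmcs <- function(cpg, samples, group_a, group_b, min_cov = 10,
                      q_max = 0.01, diff_min = 25,
                      qvalue_fun = function(p) p.adjust(p, method = "BH")) {
  sa <- group_samples(samples, group_a)
  sb <- group_samples(samples, group_b)
  wide <- cpg_wide(cpg, c(sa, sb))
  cov_a <- wide$cov[, sa, drop = FALSE]
  cov_b <- wide$cov[, sb, drop = FALSE]
  meth_a <- wide$meth[, sa, drop = FALSE]
  meth_b <- wide$meth[, sb, drop = FALSE]

  ok <- rowSums(cov_a < min_cov) == 0 & rowSums(cov_b < min_cov) == 0 &
    rowSums(cov_a) > 0 & rowSums(cov_b) > 0
  if (!any(ok)) {
    warn("no CpG site passes the coverage filter.")
    return(tibble::tibble(chrom = character(0), pos = integer(0),
                          strand = character(0), meth_diff = numeric(0),
                          p_raw = numeric(0), q_value = numeric(0),
                          is_dmc = logical(0)))
  }
  sites <- wide$sites[ok, ]
  ma <- rowSums(meth_a[ok, , drop = FALSE])
  ca <- rowSums(cov_a[ok, , drop = FALSE])
  mb <- rowSums(meth_b[ok, , drop = FALSE])
  cb <- rowSums(cov_b[ok, , drop = FALSE])
  diff <- 100 * (mb / cb - ma / ca)
  if (length(sa) == 1 && length(sb) == 1) {
    p <- purrr::map_dbl(seq_along(ma),
                        ~ fisher_two_sided(ma[.x], ca[.x], mb[.x], cb[.x]))
  } else {
    p <- binom_lrt(ma, ca, mb, cb)
  }
  q <- qvalue_fun(p)
  dplyr::bind_cols(
    sites,
    tibble::tibble(meth_diff = diff, p_raw = p, q_value = q,
                   is_dmc = q <= q_max & abs(diff) >= diff_min)
  )
}

# site x sample coverage and methylation matrices for the named samples
cpg_wide <- function(cpg, use_samples) {
  d <- dplyr::filter(cpg, .data$sample %in% use_samples)
  missing <- setdiff(use_samples, unique(d$sample))
  if (length(missing) > 0)
    abort(paste0("samples absent from CpG table: ",
                 paste(missing, collapse = ", ")))
  key <- paste(d$chrom, d$pos, d$strand, sep = "\r")
  ukey <- unique(key)
  i <- match(key, ukey)
  j <- match(d$sample, use_samples)
  cov <- meth <- matrix(0L, length(ukey), length(use_samples),
                        dimnames = list(NULL, use_samples))
  cov[cbind(i, j)] <- d$coverage
  meth[cbind(i, j)] <- d$meth_count
  first <- !duplicated(key)
  sites <- tibble::tibble(chrom = d$chrom[first], pos = d$pos[first],
                          strand = d$strand[first])
  list(sites = sites, cov = cov, meth = meth)
}
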