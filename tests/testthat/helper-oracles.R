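# Independent oracles, coded from first principles and kept deliberately
# naive so they share no code path with the package implementation.

# Two-sided Fisher exact p from log-factorials: enumerate every table with
# the observed margins and sum the probabilities of those no more likely
# than the observed table.
oracle_fisher_p <- function(m1, c1, m2, c2) {
  k <- m1 + m2
  xs <- max(0, k - c2):min(k, c1)
  logp <- lchoose(c1, xs) + lchoose(c2, k - xs) - lchoose(c1 + c2, k)
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(m1, xs)]
  sum(p[p <= obs * (1 + 1e-7)])
}

# Log-rank chi-square by literal risk-set enumeration.
oracle_logrank_chi2 <- function(group, time, event) {
  g1 <- group == sort(unique(group))[1]
  omE <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    omE <- omE + (d1 - d * n1 / n)
    if (n > 1)
      V <- V + d * (n1 / n) * ((n - n1) / n) * (n - d) / (n - 1)
  }
  if (V == 0) 0 else omE^2 / V
}

# Per-site linear scan over every gene: is the position inside the
# promoter (TSS +/- flank) or the body (past TSS + flank up to the
# terminus, walking in transcription direction)?
oracle_assign <- function(chrom, pos, annotation, flank = 500) {
  out <- list()
  for (i in seq_len(nrow(annotation))) {
    g <- annotation[i, ]
    if (g$chrom != chrom) next
    d <- if (g$strand == "+") pos - g$tss else g$tss - pos
    if (d >= -flank && d <= flank) {
      out[[length(out) + 1]] <- c(g$gene_id, "promoter")
    } else if (d > flank) {
      gene_len <- g$tx_end - g$tx_start + 1
      if (d <= gene_len - 1)
        out[[length(out) + 1]] <- c(g$gene_id, "body")
    }
  }
  if (length(out) == 0) {
    tibble::tibble(gene_id = character(0), region = character(0))
  } else {
    m <- do.call(rbind, out)
    tibble::tibble(gene_id = m[, 1], region = m[, 2])
  }
}

# Brute-force integration: loop over genes, apply the direction rules and
# the dual-region exclusion literally.
oracle_integrate <- function(de_dir, region_calls, threshold = 20) {
  kept <- list()
  for (g in unique(c(names(de_dir), region_calls$gene_id))) {
    rc <- region_calls[region_calls$gene_id == g, ]
    if (nrow(rc) == 0 || is.null(de_dir[[g]])) next
    has_both <- all(c("promoter", "body") %in% rc$region)
    if (has_both && max(abs(rc$meth_diff_summary)) > threshold) next
    for (j in seq_len(nrow(rc))) {
      if (rc$discordant[j]) next
      meth_dir <- if (rc$meth_diff_summary[j] >= 0) "hyper" else "hypo"
      ok <- (rc$region[j] == "promoter" && meth_dir != "none" &&
               ((meth_dir == "hypo" && de_dir[[g]] == "up") ||
                  (meth_dir == "hyper" && de_dir[[g]] == "down"))) ||
        (rc$region[j] == "body" &&
           ((meth_dir == "hyper" && de_dir[[g]] == "up") ||
              (meth_dir == "hypo" && de_dir[[g]] == "down")))
      if (ok)
        kept[[length(kept) + 1]] <-
          tibble::tibble(gene_id = g, region = rc$region[j],
                         expr_direction = de_dir[[g]])
    }
  }
  if (length(kept) == 0) {
    tibble::tibble(gene_id = character(0), region = character(0),
                   expr_direction = character(0))
  } else {
    dplyr::arrange(dplyr::bind_rows(kept), gene_id, region)
  }
}

# Brute-force signature membership: loop genes x comparisons on a
# membership table (gene_id, group_a, group_b, expr_direction).
oracle_signatures <- function(members) {
  has <- function(g, a, b, dir) {
    any(members$gene_id == g & members$group_a == a &
          members$group_b == b & members$expr_direction == dir)
  }
  present_any <- function(g, a, b) {
    any(members$gene_id == g & members$group_a == a & members$group_b == b)
  }
  genes <- unique(members$gene_id)
  mal <- emt <- met <- list()
  for (g in genes) {
    for (dir in c("up", "down")) {
      anti <- if (dir == "up") "down" else "up"
      if (has(g, "melan-a", "4C", dir) && has(g, "melan-a", "4C11-", dir) &&
          has(g, "melan-a", "4C11+", dir))
        mal[[length(mal) + 1]] <- c(g, dir)
      if (has(g, "melan-a", "4C", dir) && has(g, "melan-a", "4C11-", dir) &&
          has(g, "4C", "4C11+", anti) && has(g, "4C11-", "4C11+", anti))
        emt[[length(emt) + 1]] <- c(g, dir)
      if (has(g, "melan-a", "4C11+", dir) && has(g, "4C", "4C11+", dir) &&
          has(g, "4C11-", "4C11+", dir) &&
          !present_any(g, "melan-a", "4C") &&
          !present_any(g, "melan-a", "4C11-"))
        met[[length(met) + 1]] <- c(g, dir)
    }
  }
  as_tbl <- function(x) {
    if (length(x) == 0)
      return(tibble::tibble(gene_id = character(0),
                            direction = character(0)))
    m <- do.call(rbind, x)
    dplyr::arrange(tibble::tibble(gene_id = m[, 1], direction = m[, 2]),
                   gene_id)
  }
  list(malignancy = as_tbl(mal), emt = as_tbl(emt), metastasis = as_tbl(met))
}

# random integrated-table generator for the set-algebra equivalence tests
random_integrated <- function(n_genes = 30, p_member = 0.3) {
  comps <- list(c("melan-a", "4C"), c("melan-a", "4C11-"),
                c("melan-a", "4C11+"), c("4C", "4C11+"),
                c("4C11-", "4C11+"), c("4C", "4C11-"))
  rows <- list()
  for (cp in comps) {
    sel <- runif(n_genes) < p_member
    if (!any(sel)) {
      # keep every comparison non-empty so the strict presence checks run
      sel[sample.int(n_genes, 1)] <- TRUE
    }
    ids <- sprintf("g%03d", which(sel))
    rows[[length(rows) + 1]] <- tibble::tibble(
      gene_id = ids, group_a = cp[1], group_b = cp[2],
      expr_direction = sample(c("up", "down"), length(ids), replace = TRUE),
      region = sample(c("promoter", "body"), length(ids), replace = TRUE),
      mode = "x", log2fc = 0, meth_diff_summary = 0,
      meth_direction = "hyper"
    )
  }
  dplyr::bind_rows(rows)
}
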