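#' Simulate a gene annotation and CpG site catalogue
#'
#' Lays out non-overlapping genes on `n_chroms` chromosomes with
#' inter-genic gaps large enough that promoter windows never touch a
#' neighbouring gene, then drops CpG sites at regular spacing through each
#' gene's promoter (TSS +/- `flank`) and body (TSS+`flank`+1 .. terminus).
#' Both strands are represented among genes; CpG sites alternate strands.
#'
#' @param n_genes Number of genes (>= 1).
#' @param n_chroms Number of chromosomes to spread genes over.
#' @param gene_length_range Two integers, min/max gene length in bp.
#' @param cpg_spacing Distance between consecutive CpG sites in bp.
#' @param flank Promoter half-width around the TSS in bp.
#' @param min_cpg Minimum CpG sites required per promoter and per body;
#'   infeasible spacing/length combinations error.
#' @param seed Integer seed; the same seed reproduces the catalogue exactly.
#' @return List with `annotation` (tibble as [read_annotation()]) and
#'   `cpg_sites` (tibble `chrom`, `pos`, `strand`).
#' @export
sim_annotation <- function(n_genes, n_chroms = 4,
                           gene_length_range = c(4000, 8000),
                           cpg_spacing = 150, flank = 500, min_cpg = 6,
                           seed = 1) {
  stopifnot(n_genes >= 1, n_chroms >= 1, cpg_spacing >= 1)
  n_prom <- floor(2 * flank / cpg_spacing) + 1
  min_len <- min(gene_length_range)
  n_body_min <- floor((min_len - flank - 2) / cpg_spacing) + 1
  if (n_prom < min_cpg || n_body_min < min_cpg)
    abort(paste0("infeasible cpg_spacing for the requested gene lengths: ",
                 "promoter holds ", n_prom, " and shortest body ",
                 n_body_min, " sites; need >= ", min_cpg, " each."))

  set.seed(child_seed(seed, "annotation"))
  chrom <- paste0("chr", rep_len(seq_len(n_chroms), n_genes))
  len <- sample(seq(gene_length_range[1], gene_length_range[2]), n_genes,
                replace = TRUE)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  gap <- sample(2000:4000, n_genes, replace = TRUE)

  ann <- tibble::tibble(gene_id = sprintf("gene%04d", seq_len(n_genes)),
                        chrom = chrom, strand = strand, len = len,
                        gap = gap) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      tx_start = as.integer(flank + 1000 +
                              cumsum(dplyr::lag(.data$len, default = 0L) +
                                       .data$gap) - .data$gap[1] + 1),
      tx_end = as.integer(.data$tx_start + .data$len - 1L)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"len", -"gap") |>
    validate_annotation()

  cpg <- purrr::pmap(ann, function(gene_id, chrom, strand, tx_start, tx_end,
                                   tss, tx_terminus) {
    # distances from the TSS in transcription orientation
    d_prom <- seq(-flank, flank, by = cpg_spacing)
    body_len <- (tx_end - tx_start + 1L) - flank - 1L
    d_body <- seq(flank + 1, flank + body_len, by = cpg_spacing)
    d <- c(d_prom, d_body)
    pos <- if (strand == "+") tss + d else tss - d
    tibble::tibble(chrom = chrom, pos = as.integer(pos))
  }) |> dplyr::bind_rows()
  cpg <- dplyr::arrange(cpg, .data$chrom, .data$pos) |>
    dplyr::mutate(strand = rep_len(c("+", "-"), dplyr::n()))

  list(annotation = ann, cpg_sites = cpg)
}

coupling_modes <- function() {
  tibble::tibble(
    mode = c("promoter-hypo-up", "promoter-hyper-down",
             "body-hyper-up", "body-hypo-down"),
    region = c("promoter", "promoter", "body", "body"),
    meth_sign = c(-1, 1, 1, -1),
    expr_sign = c(1, -1, 1, -1)
  )
}

decoy_modes <- function() {
  # sign pairings that violate the regulatory direction rules by construction
  tibble::tibble(
    mode = c("decoy-promoter-hyper-up", "decoy-body-hypo-up"),
    region = c("promoter", "body"),
    meth_sign = c(1, -1),
    expr_sign = c(1, 1)
  )
}

truth_row <- function(gene_id, archetype, mode, region, log2fc, delta_meth,
                      groups) {
  tibble::tibble(gene_id = gene_id, archetype = archetype, mode = mode,
                 region = region, log2fc = log2fc, delta_meth = delta_meth,
                 affected_groups = paste(groups, collapse = ","))
}

fill_null <- function(truth, annotation) {
  rest <- setdiff(annotation$gene_id, truth$gene_id)
  dplyr::bind_rows(
    truth,
    tibble::tibble(gene_id = rest, archetype = "null", mode = "null",
                   region = "none", log2fc = 0, delta_meth = 0,
                   affected_groups = "")
  ) |> dplyr::arrange(.data$gene_id)
}

#' Planted truth: no effects anywhere
#' @param annotation Annotation tibble.
#' @return Truth tibble (`gene_id`, `archetype`, `mode`, `region`,
#'   `log2fc`, `delta_meth`, `affected_groups`).
#' @export
plant_null <- function(annotation) {
  fill_null(truth_row(character(0), character(0), character(0),
                      character(0), numeric(0), numeric(0), character(0)),
            annotation)
}

#' Planted truth: coupled genes for one pairwise comparison
#'
#' Plants `n_per_mode` genes in each of the four concordant coupling modes
#' (promoter hypo -> up, promoter hyper -> down, body hyper -> up, body
#' hypo -> down) plus optional decoy genes whose methylation/expression
#' sign pairing violates the direction rules. Effects apply in
#' `groups_affected`; all remaining genes are null. Equal allocation across
#' the four modes keeps the planted log2 fold changes sign-balanced, so
#' column-sum library sizes stay comparable between groups.
#'
#' @param annotation Annotation tibble.
#' @param n_per_mode Genes planted per concordant mode.
#' @param groups_affected Group labels whose samples carry the effect.
#' @param log2fc Absolute planted expression effect (log2).
#' @param delta_meth Absolute planted methylation shift, percentage points.
#' @param n_decoy Decoy-discordant genes (split over the two decoy modes).
#' @param seed Integer seed for the random gene assignment.
#' @return Truth tibble covering every annotated gene.
#' @export
plant_coupled <- function(annotation, n_per_mode = 50,
                          groups_affected = "4C11+", log2fc = 3,
                          delta_meth = 40, n_decoy = 0, seed = 1) {
  modes <- coupling_modes()
  dec <- decoy_modes()
  n_tot <- n_per_mode * nrow(modes) + n_decoy
  if (n_tot > nrow(annotation))
    abort("more planted genes than genes in the annotation.")
  set.seed(child_seed(seed, "truth"))
  picks <- sample(annotation$gene_id, n_tot)
  rows <- purrr::map(seq_len(nrow(modes)), function(i) {
    ids <- picks[seq_len(n_per_mode) + (i - 1) * n_per_mode]
    truth_row(ids, "coupled", modes$mode[i], modes$region[i],
              log2fc * modes$expr_sign[i], delta_meth * modes$meth_sign[i],
              groups_affected)
  })
  if (n_decoy > 0) {
    ids <- picks[n_per_mode * nrow(modes) + seq_len(n_decoy)]
    di <- rep_len(seq_len(nrow(dec)), n_decoy)
    rows <- c(rows, list(
      truth_row(ids, "decoy-discordant", dec$mode[di], dec$region[di],
                log2fc * dec$expr_sign[di], delta_meth * dec$meth_sign[di],
                groups_affected)))
  }
  fill_null(dplyr::bind_rows(rows), annotation)
}

#' Planted truth: progression-signature archetypes
#'
#' Plants genes whose group pattern matches each signature of the
#' progression model: malignancy (shifted in 4C, 4C11- and 4C11+ relative
#' to melan-a), EMT (shifted only in the mesenchymal pair 4C/4C11-) and
#' metastasis (shifted only in 4C11+). Each archetype is planted in both
#' directions; promoter and body coupling alternate within an archetype.
#'
#' @param annotation Annotation tibble.
#' @param n_each Genes planted per archetype and direction (6 cells).
#' @param log2fc,delta_meth Absolute effect sizes as in [plant_coupled()].
#' @param seed Integer seed.
#' @return Truth tibble covering every annotated gene; `archetype` is one
#'   of `malignancy-up`, `malignancy-down`, `emt-up`, `emt-down`,
#'   `metastasis-up`, `metastasis-down`, `null`.
#' @export
plant_archetypes <- function(annotation, n_each = 10, log2fc = 3,
                             delta_meth = 40, seed = 1) {
  arch <- tibble::tribble(
    ~archetype, ~dir, ~groups,
    "malignancy", 1, c("4C", "4C11-", "4C11+"),
    "malignancy", -1, c("4C", "4C11-", "4C11+"),
    "emt", 1, c("4C", "4C11-"),
    "emt", -1, c("4C", "4C11-"),
    "metastasis", 1, c("4C11+"),
    "metastasis", -1, c("4C11+")
  )
  n_tot <- n_each * nrow(arch)
  if (n_tot > nrow(annotation))
    abort("more planted genes than genes in the annotation.")
  set.seed(child_seed(seed, "truth"))
  picks <- sample(annotation$gene_id, n_tot)
  modes <- coupling_modes()
  rows <- purrr::map(seq_len(nrow(arch)), function(i) {
    ids <- picks[seq_len(n_each) + (i - 1) * n_each]
    want <- modes[modes$expr_sign == arch$dir[i], ]
    mi <- rep_len(seq_len(nrow(want)), n_each)
    truth_row(ids, paste0(arch$archetype[i],
                          ifelse(arch$dir[i] > 0, "-up", "-down")),
              want$mode[mi], want$region[mi],
              log2fc * arch$dir[i], delta_meth * want$meth_sign[mi],
              arch$groups[[i]])
  })
  fill_null(dplyr::bind_rows(rows), annotation)
}

make_sample_sheet <- function(groups, reps_per_group) {
  tibble::tibble(
    sample = paste0(rep(groups, each = reps_per_group), "_r",
                    rep(seq_len(reps_per_group), length(groups))),
    group = rep(groups, each = reps_per_group)
  )
}

affected_lookup <- function(truth, groups) {
  # logical matrix gene x group: does this gene's effect apply in the group?
  aff <- matrix(FALSE, nrow(truth), length(groups),
                dimnames = list(truth$gene_id, groups))
  lst <- strsplit(truth$affected_groups, ",", fixed = TRUE)
  for (i in seq_along(lst)) aff[i, intersect(lst[[i]], groups)] <- TRUE
  aff
}

#' Simulate a grouped RNA-seq count matrix
#'
#' Negative-binomial counts for `length(groups) * reps_per_group` samples;
#' the group design mirrors the four-cell-line, triplicate layout of the
#' progression model. Planted genes have their mean multiplied by
#' `2^log2fc` in affected groups; all genes share `baseline_mean` and a
#' fixed dispersion, so library sizes are equal up to NB noise.
#'
#' @param annotation Annotation tibble.
#' @param truth Planted-truth tibble (see [plant_coupled()]).
#' @param groups Group labels, default the four progression lines.
#' @param reps_per_group Replicates per group.
#' @param baseline_mean Mean count of an unaffected gene.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param seed Integer seed.
#' @return List with `counts` (tibble `gene_id` + sample columns) and
#'   `samples` (sample sheet).
#' @export
simulate_counts <- function(annotation, truth = plant_null(annotation),
                            groups = progression_lines(),
                            reps_per_group = 3, baseline_mean = 100,
                            dispersion = 0.1, seed = 1) {
  stopifnot(dispersion > 0, reps_per_group >= 1, baseline_mean > 0)
  truth <- truth[match(annotation$gene_id, truth$gene_id), ]
  samples <- make_sample_sheet(groups, reps_per_group)
  aff <- affected_lookup(truth, groups)
  mult <- ifelse(aff, 2^truth$log2fc, 1)     # gene x group
  mu <- baseline_mean * mult[, samples$group, drop = FALSE]
  set.seed(child_seed(seed, "counts"))
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                nrow = nrow(mu), dimnames = list(NULL, samples$sample))
  counts <- dplyr::bind_cols(tibble::tibble(gene_id = annotation$gene_id),
                             tibble::as_tibble(cnt))
  list(counts = counts, samples = samples)
}

#' Simulate a beta-binomial CpG methylome
#'
#' Per site and sample, coverage is shifted Poisson (minimum 1) and the
#' methylated count is binomial with a beta-distributed success
#' probability: mean = the group-level methylation, precision = `precision`
#' (replicate-to-replicate overdispersion; at precision 300 and mean 0.5
#' the replicate s.d. is about 3 percentage points, typical of isogenic
#' cultured triplicates). All CpGs of a planted gene's region shift by
#' `delta_meth` percentage points in affected groups, clipped to
#' [0.02, 0.98] with a warning.
#'
#' @inheritParams simulate_counts
#' @param cpg_sites CpG catalogue from [sim_annotation()].
#' @param coverage_mean Mean read coverage per site and sample.
#' @param baseline_beta Baseline methylation level in (0, 1).
#' @param precision Beta precision (a + b) of replicate variation.
#' @param flank Promoter half-width used to map sites to regions.
#' @return List with `cpg` (long tibble as [read_cpg_tables()]) and
#'   `samples` (sample sheet).
#' @export
simulate_methylome <- function(annotation, cpg_sites,
                               truth = plant_null(annotation),
                               groups = progression_lines(),
                               reps_per_group = 3, coverage_mean = 30,
                               baseline_beta = 0.5, precision = 300,
                               seed = 1, flank = 500) {
  stopifnot(baseline_beta > 0, baseline_beta < 1, precision > 0,
            coverage_mean >= 1)
  samples <- make_sample_sheet(groups, reps_per_group)
  site_map <- assign_regions(cpg_sites, annotation, flank = flank)

  mu <- matrix(baseline_beta, nrow(cpg_sites), length(groups),
               dimnames = list(NULL, groups))
  site_key <- paste(cpg_sites$chrom, cpg_sites$pos, cpg_sites$strand)
  planted <- dplyr::filter(truth, .data$delta_meth != 0)
  if (nrow(planted) > 0) {
    hits <- dplyr::inner_join(
      site_map, planted, by = c("gene_id", "region")
    )
    idx <- match(paste(hits$chrom, hits$pos, hits$strand), site_key)
    lst <- strsplit(hits$affected_groups, ",", fixed = TRUE)
    for (g in groups) {
      in_g <- purrr::map_lgl(lst, ~ g %in% .x)
      mu[idx[in_g], g] <- mu[idx[in_g], g] + hits$delta_meth[in_g] / 100
    }
    if (any(mu < 0.02 | mu > 0.98)) {
      warn("planted methylation shifts clipped to [0.02, 0.98].")
      mu <- pmin(pmax(mu, 0.02), 0.98)
    }
  }

  set.seed(child_seed(seed, "methylome"))
  mu_s <- mu[, samples$group, drop = FALSE]
  cov <- matrix(rpois(length(mu_s), coverage_mean - 1) + 1L, nrow(mu_s))
  p <- matrix(rbeta(length(mu_s), mu_s * precision, (1 - mu_s) * precision),
              nrow(mu_s))
  meth <- matrix(rbinom(length(mu_s), cov, p), nrow(mu_s))

  cpg <- tibble::tibble(
    chrom = rep(cpg_sites$chrom, times = nrow(samples)),
    pos = rep(cpg_sites$pos, times = nrow(samples)),
    strand = rep(cpg_sites$strand, times = nrow(samples)),
    sample = rep(samples$sample, each = nrow(cpg_sites)),
    coverage = as.integer(cov),
    meth_count = as.integer(meth)
  )
  list(cpg = cpg, samples = samples)
}

#' Simulate a survival cohort driven by a planted signature score
#'
#' Generates standard-normal expression for every signature gene plus
#' `n_noise_features` unrelated genes, computes the combined signature
#' score exactly as [signature_score()] defines it, and draws exponential
#' event times with hazard `baseline_hazard * exp(beta_per_sd * score)`
#' (the proportional-hazards generative model the Cox stage assumes).
#' Censoring is independent exponential, calibrated so that roughly
#' `censor_rate` of patients are censored when `beta_per_sd` is small.
#' Two synthetic covariates are attached: a lognormal Breslow-like
#' thickness positively tied to the score and a T-cell-like score
#' negatively tied to it.
#'
#' @param signature An `epi_signature` (see [signature_malignancy()]) or a
#'   tibble with columns `gene_id`, `direction`.
#' @param n_patients Cohort size (>= 10).
#' @param beta_per_sd True log-hazard coefficient per standard deviation of
#'   the combined score; `true_score` in the output is the standardized
#'   score, so a Cox fit on it estimates exactly this value.
#' @param baseline_hazard Baseline exponential hazard (per year).
#' @param censor_rate Target censoring fraction in (0, 1).
#' @param n_noise_features Unrelated features added to the matrix.
#' @param seed Integer seed.
#' @return List with `clinical` (tibble `patient_id`, `time_years`,
#'   `event`, `breslow_thickness`, `tcell_score`, `true_score`) and
#'   `matrix` (tibble `feature` + patient columns).
#' @export
simulate_cohort <- function(signature, n_patients = 703,
                            beta_per_sd = log(1.49), baseline_hazard = 0.1,
                            censor_rate = 0.3, n_noise_features = 100,
                            seed = 1) {
  sig <- as_signature_tbl(signature)
  if (nrow(sig) == 0) abort("empty signature: nothing to score.")
  if (n_patients < 10) abort("n_patients must be >= 10.")
  stopifnot(censor_rate >= 0, censor_rate < 1, baseline_hazard > 0)

  set.seed(child_seed(seed, "cohort"))
  feats <- c(sig$gene_id,
             if (n_noise_features > 0) sprintf("noise%04d",
                                               seq_len(n_noise_features)))
  pats <- sprintf("P%04d", seq_len(n_patients))
  mat <- matrix(rnorm(length(feats) * n_patients), length(feats),
                dimnames = list(NULL, pats))
  expr <- dplyr::bind_cols(tibble::tibble(feature = feats),
                           tibble::as_tibble(mat))

  score <- signature_score(zscore_matrix(expr), sig)$combined_score
  # beta_per_sd is the log-hazard per standard deviation of the combined
  # score, so the hazard uses the standardized score
  score <- score / stats::sd(score)
  hz <- baseline_hazard * exp(beta_per_sd * score)
  t_event <- rexp(n_patients, hz)
  if (censor_rate > 0) {
    t_cens <- rexp(n_patients,
                   baseline_hazard * censor_rate / (1 - censor_rate))
  } else {
    t_cens <- rep(Inf, n_patients)
  }
  clinical <- tibble::tibble(
    patient_id = pats,
    time_years = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    breslow_thickness = exp(0.6 + 0.3 * score + 0.5 * rnorm(n_patients)),
    tcell_score = -0.3 * score + rnorm(n_patients),
    true_score = score
  )
  list(clinical = clinical, matrix = expr)
}
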