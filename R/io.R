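#' Read per-sample CpG methylation call files
#'
#' Reads one methylKit-style text file per sample (columns `chrBase`, `chr`,
#' `base`, `strand`, `coverage`, `freqC`, `freqT`; tab-separated, with
#' header) into a single long table of per-CpG counts. Methylated read
#' counts are recovered from the stored percentages as
#' `round(coverage * freqC / 100)`. Sites observed in only some samples are
#' kept, with coverage 0 in the samples that lack them, so downstream
#' coverage filters see the full union of sites.
#'
#' @param paths Named character vector of file paths; names are sample ids.
#' @param samples Sample sheet: data frame with columns `sample`, `group`.
#'   Every name of `paths` must appear.
#' @return A tibble with columns `chrom`, `pos` (1-based), `strand`
#'   (`+`/`-`), `sample`, `coverage`, `meth_count`, one row per site and
#'   sample.
#' @export
read_cpg_tables <- function(paths, samples) {
  samples <- assert_sample_sheet(samples)
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    abort("`paths` must be a named character vector (names = sample ids).")
  missing <- setdiff(names(paths), samples$sample)
  if (length(missing) > 0)
    abort(paste0("samples missing from sample sheet: ",
                 paste(missing, collapse = ", ")))

  tabs <- purrr::imap(paths, read_one_cpg_file)
  long <- dplyr::bind_rows(tabs, .id = "sample")
  # union semantics: absent (site, sample) pairs become coverage 0
  sites <- dplyr::distinct(long[c("chrom", "pos", "strand")])
  grid <- tidyr::crossing(sites, sample = names(paths))
  long <- dplyr::left_join(grid, long,
                           by = c("chrom", "pos", "strand", "sample")) |>
    dplyr::mutate(
      coverage = dplyr::coalesce(.data$coverage, 0L),
      meth_count = dplyr::coalesce(.data$meth_count, 0L)
    )
  dplyr::select(long, "chrom", "pos", "strand", "sample", "coverage",
                "meth_count") |>
    dplyr::arrange(.data$chrom, .data$pos, .data$strand, .data$sample)
}

read_one_cpg_file <- function(path, sample_id) {
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrBase = readr::col_character(), chr = readr::col_character(),
      base = readr::col_double(), strand = readr::col_character(),
      coverage = readr::col_double(), freqC = readr::col_double(),
      freqT = readr::col_double()
    ),
    progress = FALSE
  )
  need <- c("chrBase", "chr", "base", "strand", "coverage", "freqC", "freqT")
  if (!all(need %in% names(raw)))
    abort(paste0("file '", path, "': expected columns ",
                 paste(need, collapse = ", ")))
  bad <- which(!complete.cases(raw[need]) | raw$coverage < 0 |
                 raw$base != round(raw$base) | raw$base < 1 |
                 !(raw$strand %in% c("F", "R", "+", "-")))
  if (length(bad) > 0)
    abort(paste0("file '", path, "', line ", bad[1] + 1L,
                 ": malformed CpG record."))
  off <- which(abs(raw$freqC + raw$freqT - 100) > 0.5)
  if (length(off) > 0)
    abort(paste0("file '", path, "', line ", off[1] + 1L,
                 ": freqC + freqT = ", raw$freqC[off[1]] + raw$freqT[off[1]],
                 " deviates from 100 by more than 0.5."))
  strand <- dplyr::recode(raw$strand, F = "+", R = "-")
  if (anyDuplicated(paste(raw$chr, raw$base, strand)))
    abort(paste0("file '", path, "': duplicate CpG positions."))
  tibble::tibble(
    chrom = raw$chr,
    pos = as.integer(raw$base),
    strand = strand,
    coverage = as.integer(raw$coverage),
    meth_count = as.integer(round(raw$coverage * raw$freqC / 100))
  )
}

#' Write per-sample CpG methylation call files
#'
#' Inverse of [read_cpg_tables()]: writes one methylKit-style file per
#' sample. Rows with zero coverage in a sample (union padding) are omitted
#' from that sample's file.
#'
#' @param cpg Long CpG tibble as returned by [read_cpg_tables()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cpg_tables <- function(cpg, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (s in unique(cpg$sample)) {
    d <- dplyr::filter(cpg, .data$sample == s, .data$coverage > 0)
    freqC <- round(100 * d$meth_count / d$coverage, 2)
    out <- tibble::tibble(
      chrBase = paste0(d$chrom, ".", d$pos), chr = d$chrom, base = d$pos,
      strand = dplyr::recode(d$strand, `+` = "F", `-` = "R"),
      coverage = d$coverage, freqC = freqC, freqT = round(100 - freqC, 2)
    )
    p <- file.path(dir, paste0(s, "_cpg.txt"))
    readr::write_tsv(out, p, progress = FALSE)
    paths[s] <- p
  }
  invisible(paths)
}

#' Read a gene annotation table
#'
#' Expects a TSV with header `gene_id`, `chrom`, `strand`, `txStart`,
#' `txEnd` (1-based, inclusive). Derives the transcription start site
#' (`tss`; `txStart` on `+`, `txEnd` on `-`) and the opposite terminus
#' (`tx_terminus`).
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `tx_start`,
#'   `tx_end`, `tss`, `tx_terminus`.
#' @export
read_annotation <- function(path) {
  raw <- readr::read_tsv(path, col_types = "cccdd", progress = FALSE)
  need <- c("gene_id", "chrom", "strand", "txStart", "txEnd")
  if (!all(need %in% names(raw)))
    abort(paste0("annotation '", path, "': expected columns ",
                 paste(need, collapse = ", ")))
  ann <- tibble::tibble(
    gene_id = raw$gene_id, chrom = raw$chrom, strand = raw$strand,
    tx_start = as.integer(raw$txStart), tx_end = as.integer(raw$txEnd)
  )
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  if (!all(ann$strand %in% c("+", "-")))
    abort("annotation: strand must be '+' or '-'.")
  if (any(ann$tx_start > ann$tx_end))
    abort("annotation: txStart > txEnd.")
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup) > 0)
    abort(paste0("annotation: duplicate gene_id: ", dup[1]))
  dplyr::mutate(
    ann,
    tss = ifelse(.data$strand == "+", .data$tx_start, .data$tx_end),
    tx_terminus = ifelse(.data$strand == "+", .data$tx_end, .data$tx_start)
  )
}

#' Write a gene annotation table
#' @param ann Annotation tibble (see [read_annotation()]).
#' @param path Output TSV path.
#' @export
write_annotation <- function(ann, path) {
  readr::write_tsv(
    tibble::tibble(gene_id = ann$gene_id, chrom = ann$chrom,
                   strand = ann$strand, txStart = ann$tx_start,
                   txEnd = ann$tx_end),
    path, progress = FALSE
  )
  invisible(path)
}

#' Read a gene-level count matrix
#'
#' TSV with a `gene_id` column and one integer column per sample.
#'
#' @param path Path to the TSV file.
#' @param samples Optional sample sheet; when given, every count column must
#'   appear in it.
#' @return Tibble `gene_id` + one integer column per sample.
#' @export
read_counts <- function(path, samples = NULL) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (!"gene_id" %in% names(raw)) abort("count matrix needs a gene_id column.")
  mat <- dplyr::select(raw, -"gene_id")
  vals <- as.matrix(mat)
  if (anyNA(vals) || any(vals < 0) || any(vals != round(vals)))
    abort("counts must be non-negative integers.")
  if (!is.null(samples)) {
    samples <- assert_sample_sheet(samples)
    missing <- setdiff(names(mat), samples$sample)
    if (length(missing) > 0)
      abort(paste0("count columns missing from sample sheet: ",
                   paste(missing, collapse = ", ")))
  }
  dplyr::mutate(raw, dplyr::across(-"gene_id", as.integer))
}

#' Read a patient cohort (survival table + feature matrix)
#'
#' The clinical table is a TSV with columns `patient_id`, `time_years`
#' (> 0), `event` (0/1) and any further numeric covariate columns. The
#' matrix is a TSV with a `feature` column (gene or CpG id) and one numeric
#' column per patient; every matrix patient must appear in the clinical
#' table.
#'
#' @param clinical_path,matrix_path Paths to the two TSV files.
#' @return List with elements `clinical` (tibble) and `matrix` (tibble).
#' @export
read_cohort <- function(clinical_path, matrix_path) {
  clin <- readr::read_tsv(clinical_path, col_types = readr::cols(
    patient_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  need <- c("patient_id", "time_years", "event")
  if (!all(need %in% names(clin)))
    abort(paste0("clinical table: expected columns ",
                 paste(need, collapse = ", ")))
  if (any(clin$time_years <= 0)) abort("clinical table: time_years must be > 0.")
  if (!all(clin$event %in% c(0, 1))) abort("clinical table: event must be 0/1.")
  if (anyDuplicated(clin$patient_id)) abort("clinical table: duplicate patient_id.")
  mat <- readr::read_tsv(matrix_path, col_types = readr::cols(
    feature = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (!"feature" %in% names(mat)) abort("cohort matrix needs a feature column.")
  orphan <- setdiff(names(mat)[-1], clin$patient_id)
  if (length(orphan) > 0)
    abort(paste0("matrix patients missing from clinical table: ",
                 paste(head(orphan, 5), collapse = ", ")))
  list(clinical = clin, matrix = mat)
}

#' Write any result tibble as TSV
#'
#' Plain TSV writer used for all pipeline outputs; [read_result()] is its
#' inverse and reproduces the tibble exactly (round-trip stable).
#'
#' @param x A data frame.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @param col_types Optional readr column specification; guessed otherwise.
#' @export
read_result <- function(path, col_types = NULL) {
  readr::read_tsv(path, col_types = col_types, progress = FALSE,
                  guess_max = 100000, show_col_types = FALSE)
}
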