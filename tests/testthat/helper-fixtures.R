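# small in-code fixtures shared across test files

tiny_annotation <- function() {
  validate_ann_tbl(tibble::tribble(
    ~gene_id, ~chrom, ~strand, ~tx_start, ~tx_end,
    "geneA", "chr1", "+", 1000L, 5000L,
    "geneB", "chr1", "-", 8000L, 12000L,
    "geneC", "chr2", "+", 500L, 3000L
  ))
}

# re-derive tss/terminus the way read_annotation does, without file IO
validate_ann_tbl <- function(ann) {
  dplyr::mutate(
    ann,
    tss = ifelse(strand == "+", tx_start, tx_end),
    tx_terminus = ifelse(strand == "+", tx_end, tx_start)
  )
}

write_methylkit_file <- function(path, chrom, pos, strand, coverage,
                                 freqC, freqT = 100 - freqC) {
  readr::write_tsv(tibble::tibble(
    chrBase = paste0(chrom, ".", pos), chr = chrom, base = pos,
    strand = strand, coverage = coverage, freqC = freqC, freqT = freqT
  ), path, progress = FALSE)
  path
}

# long CpG tibble from per-sample meth/coverage matrices
cpg_from_matrices <- function(pos, meth, cov, samples,
                              chrom = "chr1", strand = "+") {
  stopifnot(nrow(meth) == length(pos), ncol(meth) == nrow(samples))
  pos_rep <- rep(pos, times = nrow(samples))
  sample_rep <- rep(samples$sample, each = length(pos))
  tibble::tibble(
    chrom = chrom, pos = pos_rep, strand = strand, sample = sample_rep,
    coverage = as.integer(cov), meth_count = as.integer(meth)
  )
}

two_group_sheet <- function(na = 3, nb = 3, a = "A", b = "B") {
  tibble::tibble(
    sample = c(paste0(a, seq_len(na)), paste0(b, seq_len(nb))),
    group = c(rep(a, na), rep(b, nb))
  )
}
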