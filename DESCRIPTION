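Package: epiprog
Title: Methylome-Transcriptome Integration Across a Melanoma Progression Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for integrating reduced-representation bisulfite
    sequencing methylomes with RNA-seq transcriptomes across a staged
    cell-line model of melanoma progression. Provides per-CpG differential
    methylation testing, promoter and gene-body region calling,
    direction-consistent integration with differential expression,
    derivation of malignancy, EMT and metastasis gene signatures by set
    algebra over pairwise comparisons, and prognostic scoring of those
    signatures on patient cohorts (z-score signature scores, Kaplan-Meier
    and log-rank analysis, Cox proportional hazards with Efron ties,
    quartile stratification). Includes simulators for grouped
    negative-binomial counts, beta-binomial methylomes with planted
    region-level effects coupled to expression, and survival cohorts with
    hazard proportional to a planted signature score, so the full pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    ggplot2,
    generics,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    limma,
    survival,
    jsonlite,
    withr
Config/testthat/edition: 3
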