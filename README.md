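# epiprog

Integrative methylome–transcriptome analysis across a staged melanoma
progression model, with prognostic signature scoring on patient cohorts.

## What it does, and for whom

DNA methylation regulates transcription in a region-dependent way:
promoter methylation is typically repressive, while gene-body methylation
tracks active transcription. `epiprog` is for epigenomics researchers who
have per-CpG bisulfite methylation calls (ERRBS/RRBS) and RNA-seq counts
for a series of related cell lines — here the four-stage murine melanoma
model melan-a → 4C → 4C11− → 4C11+ (melanocyte, premalignant,
nonmetastatic, metastatic) — and want to

1. call differentially methylated cytosines (DMCs) and differentially
   expressed genes between pairs of lines,
2. keep only genes whose methylation and expression changes pair in the
   regulatorily coherent directions,
3. intersect those per-comparison lists into progression signatures
   (malignancy, EMT, metastasis), and
4. test the signatures' prognostic value on patient survival cohorts.

Everything is tibble-in / tibble-out and chains with the pipe; simulators
generate all inputs, so the full pipeline runs and is tested with no
external data.

## The statistics at the core

**Per-CpG differential methylation.** For site *i* with replicate counts
(methylated *m*, coverage *n*) in two groups, the test is a
likelihood-ratio test of the binomial logistic model
*m/n* ~ group against the intercept-only model (1 df); with single
replicates it falls back to the two-sided Fisher exact test. The effect is
the coverage-pooled difference Δβ = 100·(Σm_B/Σn_B − Σm_A/Σn_A) in
percentage points. A DMC requires BH *q* ≤ 0.01 and |Δβ| ≥ 25.

**Region calls.** Promoter = TSS ± 500 bp, gene body = TSS+501 … TxEnd in
gene-strand orientation. A gene region is differentially methylated when
it holds ≥ 3 DMCs; its summary is the mean member Δβ.

**Differential expression.** log2-CPM with pseudocount 0.5; an
empirical-Bayes moderated t-test (variances squeezed toward a common
prior; Welch t available as `engine = "welch"`); significance at
|log2FC| ≥ 2 and BH-adjusted *P* ≤ 0.01.

**Integration.** A gene is epigenetically regulated in a comparison when
promoter methylation moves opposite to expression (hypo→up, hyper→down)
or body methylation moves with it (hyper→up, hypo→down). Genes with both
promoter and body calls where either |Δβ| exceeds 20 points are excluded.

**Signatures.** Set algebra over the pairwise lists with
direction-consistency: malignancy = altered the same way in all three
comparisons against melan-a; EMT = up (down) in both mesenchymal lines
versus melan-a *and* down (up) again in 4C11+ versus both; metastasis =
altered the same way in 4C11+ versus all three other lines and nowhere
else.

**Survival.** Per-patient score = mean of z-transformed expression over
signature genes with −1 weighting for downregulated members:
*s* = (Σ z_up − Σ z_down) / (n_up + n_down). Prognosis via in-package Cox
partial likelihood (Newton–Raphson, Efron ties), Kaplan–Meier curves with
the log-rank test after median dichotomization, Spearman association with
covariates, and strict 25%/75% quartile stratification.

## Worked example

```r
library(epiprog)

sim   <- sim_annotation(800, seed = 1)                      # genes + CpG catalogue
truth <- plant_archetypes(sim$annotation, n_each = 10, seed = 1)
cnt   <- simulate_counts(sim$annotation, truth, seed = 1)   # NB counts, 4 x 3
met   <- simulate_methylome(sim$annotation, sim$cpg_sites, truth, seed = 1)

res <- run_progression_analysis(cnt$counts, met$cpg, cnt$samples, sim$annotation)
glance(res$signatures$metastasis)
#> # A tibble: 1 × 4
#>   signature  n_genes  n_up n_down
#>   <chr>        <int> <int>  <int>
#> 1 metastasis      20    10     10

coh    <- simulate_cohort(res$signatures$metastasis, n_patients = 703,
                          beta_per_sd = log(1.49), seed = 2)
scores <- signature_score(zscore_matrix(coh$matrix), res$signatures$metastasis)
tidy(cox_fit(coh$clinical$true_score, coh$clinical$time_years, coh$clinical$event))
#> # A tibble: 1 × 7
#>   term  estimate std.error hazard_ratio conf.low conf.high  p.value
#>   <chr>    <dbl>     <dbl>        <dbl>    <dbl>     <dbl>    <dbl>
#> 1 score    0.410    0.0489         1.51     1.37      1.66 5.12e-17

grp <- dichotomize_median(scores)
km_logrank(grp$group, coh$clinical$time_years, coh$clinical$event)
#> Log-rank test: chi2 = 49.66 (1 df), p = 1.826e-12
#> n = 703 , events = 469
```

The 60 planted archetype genes are split 20/20/20 over the three
signatures; the pipeline recovers them (20, 18, 20 members) with no
cross-signature leakage. The cohort was planted with a log-hazard of
ln(1.49) = 0.399 per score standard deviation; the Cox fit returns 0.410
(HR 1.51, CI 1.37–1.66), and the Kaplan–Meier split of high- versus
low-score patients separates at p ≈ 2e-12. `autoplot()` on the log-rank
object draws the curves; `plot_integration()` and
`plot_methylation_expression()` summarize the integrated gene lists.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the whole pipeline from scratch at the given seed — simulation,
differential expression and methylation, region calling, integration, the
three signatures, cohort scoring, Cox and log-rank — printing the fitted
summaries and writing the JSON report to `--out`.
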