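---
title: "Methods: methylome-transcriptome integration and prognostic scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome-transcriptome integration and prognostic scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiprog)
```

## The model and its assumptions

`epiprog` analyses a linear four-stage cell-line model of melanoma
progression — melan-a melanocytes, premalignant 4C, nonmetastatic
melanoma 4C11−, metastatic 4C11+ — assayed in triplicate by RNA-seq
(gene counts) and by enhanced reduced-representation bisulfite
sequencing (per-CpG methylated/total read counts). The central
assumption is the canonical region-dependent coupling between DNA
methylation and transcription: promoter methylation (TSS ± 500 bp)
represses, gene-body methylation (TSS+501 bp to the transcription end)
accompanies active transcription. The pipeline therefore treats a gene
as *epigenetically regulated* in a pairwise comparison only when the
sign pairing matches one of four modes: promoter-hypo→up,
promoter-hyper→down, body-hyper→up, body-hypo→down. "Correlation" here
is this sign pairing across two conditions, not a coefficient across
many samples — with two groups per comparison there is nothing more to
estimate.

Three signatures summarise the progression design by set algebra over
the per-comparison integrated lists, each requiring a *consistent*
expression direction in every supporting comparison:

* **malignancy** — same direction in 4C, 4C11− and 4C11+, each versus
  melan-a;
* **EMT** — up (down) in 4C and 4C11− versus melan-a and down (up) again
  in 4C11+ versus each mesenchymal line, i.e. a two-versus-two contrast
  of the mesenchymal pair against both differentiated lines. The
  melan-a versus 4C11+ comparison carries no information about this
  contrast and is ignored;
* **metastasis** — same direction in 4C11+ versus all three other lines,
  and (by default) absent from the melan-a comparisons against 4C and
  4C11−, enforcing the "only in the metastatic line" reading. The clause
  is toggleable (`exclusive = FALSE`).

Direction consistency is a deliberate design choice: a gene up in one
supporting comparison and down in another is not coherent evidence for a
signature, so it is excluded rather than counted twice.

## Statistical machinery and numerical choices

**Per-CpG test.** With replicates, a likelihood-ratio test of
`methylated/coverage ~ group` against the intercept-only binomial
logistic model. Because the only covariate is a two-level factor, the
group-wise maximum-likelihood fits are the coverage-pooled proportions,
so the statistic has a closed form and the whole methylome is tested
with vectorised arithmetic (verified against `glm()` in the tests). No
overdispersion correction is applied by default; the q-value machinery
is pluggable (`qvalue_fun`), with Benjamini–Hochberg as the default in
place of external q-value packages. With one replicate per group the
test falls back to the two-sided Fisher exact test, computed by
hypergeometric enumeration with the customary `1 + 1e-7` relative
tolerance on "as extreme". Probabilities are clamped away from 0/1
before taking logs; the LRT statistic is floored at zero against
rounding.

**Coverage filter.** Sites are tested only when *every* sample of both
groups has coverage ≥ `min_cov` (default 10, the methylKit convention).
Union padding from samples that never saw a site counts as coverage 0
and removes the site, which is the conservative reading.

**Methylation difference.** Coverage-pooled proportions
(Σm/Σn per group), not means of per-sample fractions: stable under
uneven coverage, and antisymmetric under group swap by construction.

**DMC and region thresholds.** All thresholds are inclusive as printed:
q ≤ 0.01, |Δβ| ≥ 25 points; a region call needs ≥ 3 member DMCs
(`min_cpgs` counts DMCs by default; counting tested CpGs instead is
available via `count = "tested"` since the defining phrase admits both
readings). The boundary base TSS+500 belongs to the promoter only, so
the two regions are disjoint per gene. The CpG's own strand is ignored
for assignment and opposite-strand calls are never merged. Region
summaries with mixed-sign members are flagged `discordant` and skipped
by integration unless asked otherwise.

**Coordinates.** All intervals are 1-based inclusive end to end — the
R/Bioconductor convention (GenomicRanges does the overlap work). File
formats use the same convention, so nothing is shifted on IO.

**Differential expression.** Library size is the column sum of raw
counts; expression is log2-CPM with pseudocount 0.5. The default test is
an in-package empirical-Bayes moderated t: gene-wise pooled variances
are squeezed toward a prior estimated by the method of moments on
log(s²) (prior df via the inverse trigamma; infinite prior df collapses
to the bias-corrected common variance). The plain Welch t is available
as `engine = "welch"`, but with triplicates its 2–4 residual degrees of
freedom cannot push even 8-fold changes below stringent BH thresholds —
on simulated data the moderated engine detects planted |log2FC| = 3
genes with sensitivity > 0.95 where Welch recovers almost none, and its
null p-values are uniform where Welch's are conservative. That is why
moderation is the default rather than an option. Significance uses
|log2FC| ≥ 2 and BH-adjusted P ≤ 0.01, inclusive.

**Dual-region exclusion.** A gene with both a promoter and a body call
in the same comparison is dropped when either region's |Δβ| exceeds 20
points (strict >). The defining sentence is ambiguous — it could also
mean the *difference between* the two regions' changes — so that second
reading is implemented behind `rule = "between-region"`; the
either-region reading is the default because the excluded genes it
produces are exactly those where a single dominant methylation change
spans both regions and the regulatory attribution is ambiguous. Genes
with both calls but ≤ 20-point changes stay eligible for both promoter
and body modes.

**Signature scoring.** Features are z-transformed across patients with
the sample (n−1) variance; zero-variance features are dropped with a
warning rather than propagating NaN. The combined score is the mean of
member z-scores with weight +1 (up) and −1 (down). Median
dichotomization sends ties to the low group (deterministic and
configurable by negating scores); quartile stratification uses strict
bounds (< 25th, > 75th percentile) with type-7 linear-interpolation
quantiles, pinned here for reproducibility since the original analyses
do not print their convention.

**Survival.** Kaplan–Meier, the two-group log-rank test
(χ² = (Σ(O−E))²/ΣV with hypergeometric variance) and Cox proportional
hazards are implemented in the package; the Cox solver is
Newton–Raphson on the partial likelihood with the Efron tie correction,
50-iteration cap, and explicit failure modes: singular information
(collinear covariates), divergence (|β| > 15, the separation signature),
and non-convergence all raise errors rather than returning garbage. The
`survival` package is used in the test suite as an independent oracle —
coefficients, standard errors and log-likelihoods agree to 1e-7 — but
never as the implementation.

## What the simulators emulate — and what they do not

`sim_annotation()` lays out non-overlapping genes with regularly spaced
CpGs (defaults give ≥ 6 promoter and ≥ 6 body sites per gene, both
strands represented). `simulate_counts()` draws negative-binomial counts
with fixed dispersion 0.1 — standard RNA-seq noise at the triplicate
design — multiplying means by 2^log2FC in affected groups.
`simulate_methylome()` draws coverage as a shifted Poisson (mean 30,
minimum 1) and methylated counts as beta-binomial: replicate-level
methylation is Beta with the group mean and precision 300, i.e. a
replicate-to-replicate standard deviation of ~3 percentage points at
50% methylation — our reading of realistic variation for isogenic
cultured triplicates; neither the study nor the design brief states a
value, so it is a package default, chosen once. Planted shifts apply to
every CpG of a gene's planted region and are clipped to [0.02, 0.98]
with a warning.

Planted-truth builders define the stated worlds of the tests:
`plant_coupled()` spreads planted genes *equally over the four coupling
modes*, which keeps planted fold changes sign-balanced — one-sided
planting of hundreds of 8-fold genes would inflate the affected group's
library sizes by ~0.85 log2 units and attenuate every observed fold
change, which is a property of column-sum normalization worth knowing
about, not a scenario the progression design describes. Decoy genes
carry methylation/expression pairings that violate the direction rules
and must never integrate. `plant_archetypes()` plants the three
signature patterns (effects in the appropriate group subsets, both
directions, promoter and body modes alternating).

`simulate_cohort()` draws i.i.d. standard-normal expression, computes
the combined score exactly as `signature_score()` defines it,
standardizes it, and draws exponential event times with hazard
h₀·exp(β·score) — exactly the proportional-hazards generative model the
Cox stage assumes, so parameter recovery is a meaningful check. β is
per standard deviation of the score (hence the standardization; without
it the estimand would depend on signature size). Censoring is
independent exponential calibrated to the requested rate; two synthetic
covariates (a lognormal Breslow-like thickness, a negatively coupled
T-cell-like score) support the association methods. The RNA-seq
emulation keeps three replicates for all four lines, although the
original melan-a line was sequenced in duplicate; the uniform design is
the stated world of the test-bed.

What the simulators do **not** emulate: genomic CpG density structure
(islands/shores), sequence context, read-level errors, correlated genes,
batch effects, or non-proportional hazards. A green test therefore
establishes that the machinery is correct on data satisfying its own
assumptions — not that those assumptions hold for any real cohort.

One global seed fans out to fixed per-stage child seeds (all below
2^31), so stages are individually reproducible and mutually independent.

## Known limitations

* The DE stage is two-group only: no batch correction, no multi-factor
  designs, no voom-style precision weights (the engine interface is
  pluggable for that purpose).
* The per-CpG LRT ignores replicate overdispersion; with the default
  thresholds (q ≤ 0.01 *and* |Δβ| ≥ 25) the joint filter keeps the null
  clean at realistic precision, but heavily overdispersed replicates
  would need a corrected engine behind `qvalue_fun`/`cpg_test`.
* Region calling is fixed-window (TSS ± 500, body); no islands, shores,
  enhancers, or isoform-specific TSS handling.
* Survival tooling stops at right censoring, Efron ties and Wald/
  log-rank inference: no time-varying covariates, competing risks or
  proportionality diagnostics.
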