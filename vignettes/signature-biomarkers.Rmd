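---
title: "Signature scoring and biomarker evaluation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature scoring and biomarker evaluation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigscore)
```

## The problem

Facioscapulohumeral muscular dystrophy (FSHD) is linked to derepression of the
transcription factor DUX4, whose transcript is notoriously hard to detect in
patient muscle: expression is confined to rare cells and, in differentiating
muscle, to transient bursts. Biomarker work in this field therefore leans on
*target-gene signatures* — sets of genes induced by DUX4 (early sets from ~8 h
induction experiments, late sets from 24–48 h), a PAX7 target-gene repression
contrast, and a lymphoblast-derived up-regulated set — summarized per sample
as a single scalar score and evaluated for case/control discrimination.

`sigscore` implements that pipeline as reusable, tested components:

1. **Scoring.** An unsigned set is scored as the mean expression of its genes
   in a sample. A signed set (e.g. PAX7: 311 up vs 290 down genes) is scored
   as the within-sample Welch *t* statistic contrasting up against down genes.
2. **Detection.** A sample is DUX4-positive if any normalized read is present
   (normalized count > 0) — normalization rescales counts but cannot create
   signal from zero reads, so this is the weakest faithful reading of a
   read-level detection rule.
3. **Normalization.** Scores are z-normalized (n−1 denominator) within
   matched control pairs (cell lines) or within study (biopsy cohorts), which
   is what makes scores from heterogeneous microarray/RNA-seq platforms
   poolable.
4. **Evaluation.** Wilcoxon rank-sum tests, ROC/AUC (tie-aware, equal to
   U/(n₁n₀)), and DeLong's paired AUC comparison via placement values.
5. **Meta-analysis.** Per-study mean differences of z-scores with Welch 95%
   CIs, DerSimonian–Laird random-effects pooling, and Fisher's combined test
   over the per-study Wilcoxon p-values.
6. **Association.** Pearson correlations between scores and multivariate OLS
   of each score on disease-activity covariates (three histological, three
   MRI-based).

## Statistical choices, and why

* **Welch t for the signed contrast.** Up- and down-gene sets are arbitrary
  collections with no reason to share a variance, so the unequal-variance
  form is the defensible default. Degenerate samples (zero variance on both
  sides) are an error, not a silent zero.
* **Sample standard deviations (n−1) everywhere**, including z-normalization
  within groups as small as a matched pair (n = 2, giving ±1/√2).
* **Wilcoxon modes.** Exact enumeration (via the exact U distribution) when
  the combined sample size is ≤ 12 and tie-free; otherwise the normal
  approximation with tie-corrected variance and continuity correction. The
  approximation is verified against exhaustive enumeration over all 924
  six-versus-six splits to within 0.02 in p.
* **ROC conventions.** The positive class is the case condition; higher score
  = more case-like; no automatic sign flip, so a repression biomarker shows
  AUC < 0.5, preserving directionality. Ties contribute ½, which keeps the
  AUC identical to the rank-sum U scaled by n₁n₀.
* **Meta-analysis.** Study-level variance is recovered from the Welch CI
  half-width ((hi−lo)/2 ÷ 1.96)²; τ² is the DL moment estimator truncated at
  zero; the combined test uses the per-study *two-sided* Wilcoxon p-values,
  matching the per-study tests shown alongside the forest plot. One-sided
  combination is not applied by default.
* **Signature derivation.** Genes are ranked by an OLS fit of log2 expression
  on condition + sex + matched-pair indicators, per gene, with the Wald p for
  the condition coefficient. Negative-binomial count-model machinery
  (dispersion shrinkage, independent filtering) is deliberately out of scope:
  what downstream steps consume is the *shape* of the procedure —
  covariate-adjusted ranking, top-k cut (default 500), then keeping the
  positive-effect genes. Sex is typically aliased with sex-matched pair
  indicators; the design keeps a full-rank column basis, never sacrificing
  the condition column, and errors if condition itself is confounded.
  Ordering uses raw p ascending with ties broken by |effect| then gene id,
  for determinism.
* **Quantile normalization** maps every sample onto the across-sample mean of
  sorted vectors; ties receive the mean of the reference values at their tied
  ranks. It is applied strictly within study. Note the tie rule makes exact
  idempotency hold only for tie-free data (a second pass re-averages the
  reference at tied ranks); the pinned 3×2 tie example in the tests documents
  the intended behaviour.
* **Regression.** Covariates are used as supplied (ordinal histology grades
  as numeric), listwise deletion for missingness, no multiplicity correction
  across responses by default (a Benjamini–Hochberg option exists). Collinear
  covariates produce an error naming the offending columns.

## What the synthetic generators emulate

The package generates all of its own inputs, with known ground truth.

**Multi-study cohorts** (`generate_cohort()`): seven case/control studies of
50, 30, 15, 49, 18, 22 and 43 samples (130 cases, 97 controls — per-study
splits are the generator's choice, as only totals are published for the
compendium it mirrors), a 2000-gene universe with a 237-gene signature, and

\[ x_{gj} = \mu_g + o_{s(j)} + u_j + \beta\,[\text{case}][g \in \text{sig}] + \varepsilon_{gj} \]

with study offsets \(o_s \sim N(0, 1)\), a per-sample intercept
\(u_j \sim N(0, 0.5^2)\) shared across genes (the variation that does not
average away over a signature), and residual \(\varepsilon \sim N(0, 1)\).
For an m-gene mean score the between-sample score SD is
\(\sqrt{\sigma_{pair}^2 + \sigma^2/m}\), so the planted standardized score
separation is \(\Delta = \beta / \sqrt{\sigma_{pair}^2 + \sigma^2/m}\); the
default solves β for Δ = 0.43, the separation at which the pooled AUC of
normal scores sits near 0.62 via the closed form \(AUC = \Phi(\Delta/\sqrt2)\).
Cases and controls within a study are exchangeable under the null (no
matched-pair coupling), which is what makes the unpaired per-study Wilcoxon
and the Fisher-combined null calibration meaningful. The generator emits
already-normalized log2 values, so validation loops score it directly; the
log + quantile path is exercised by the readers' own tests and the real-data
entry points.

**Matched-pair replicate designs** (`generate_paired_replicates()`): three
case/control line pairs profiled in triplicate (18 samples), sex-matched
within pair, shared within-pair baselines, 237 planted up- and 263
down-regulated genes at |log2FC| = 2, a factor transcript given positive
normalized counts in every case sample, and an optional "leak" of low counts
into replicates of one control line — mirroring a control line with
detectable transcripts in 2 of 3 replicates.

**Single-cell burst model** (`generate_burst_cells()`): each of 5133 cells is
a burst cell with probability 0.014; a burst cell observed at age
t ~ U(0, T) draws factor counts Poisson(20·e^{−t/0.1} + λ_bg) and per-gene
target counts Poisson(5·(1−e^{−t/τ}) + λ_bg) with τ = 0.2 for early and 0.5
for late targets (early targets activate faster); non-burst cells draw
Poisson(λ_bg = 10⁻⁴) everywhere. With the factor decay much faster than the
horizon, factor detection concentrates in young burst cells whose targets are
still low: across cells the factor–late-target correlation stays small while
early and late target scores correlate strongly — the dissociation seen in
single FSHD myocytes. The burst probability was fixed analytically: expected
factor detection per burst cell is ∫₀¹(1−e^{−20e^{−10t}})dt ≈ 0.357, so
p ≈ 0.014 yields an overall factor-positive fraction of ≈ 0.5%, the reported
single-cell detection rate. Uniform ages make this closed-form reasoning
possible; dropout/UMI artefacts, doublets and batch structure are
deliberately not modelled.

**What passing tests do and do not show.** The generators are Gaussian (bulk)
and Poisson (single-cell) idealizations. They validate the statistical
machinery — oracle equivalence, null calibration, parameter recovery, the
AUC link — under known truth. They do not establish biomarker performance on
real data, where platform effects, annotation mismatch and non-normal score
distributions intrude; the coverage warnings and scale tags exist precisely
because real inputs are messier.

## Numerical and validation details

* Problem sizes in the validation loops: null calibration uses 500
  seven-study replicates and 500 six-covariate regressions (n = 40);
  parameter recovery uses 200 replicates; the AUC link uses 1000 samples per
  arm; burst-model checks use 5000 cells. These sizes give Monte Carlo error
  comfortably inside the asserted bands.
* Calibration loops shrink the background gene universe (the score-level
  behaviour depends on signature size and variance components, not on how
  many background genes ride along).
* Oracle comparisons are at 1e−9; stochastic bands are stated per check
  (e.g. Fisher null rejection within [0.03, 0.07] at α = 0.05).
* Degenerate inputs error loudly: empty gene intersections, singleton or
  zero-variance z-groups, one-class ROC input, p-values at 0 entering
  Fisher's method, rank-deficient designs.
* All generators are deterministic given their seed; pipeline commands write
  a run manifest (config hash, seed, input checksums, package version).

## Known limitations

* The per-gene OLS ranking is a linear-model surrogate for count-model
  differential expression; on raw counts with strong mean–variance coupling
  its ranking will differ from a negative-binomial fit.
* DeLong's test degenerates when both score vectors induce identical
  placements (variance 0); the self-comparison convention is z = 0, p = 1.
* Fisher's combined test treats per-study p-values as independent and
  uniform; discrete Wilcoxon p's at very small study sizes make it mildly
  conservative.
* Quantile normalization assumes comparable distributions within a study; it
  is not batch correction across studies, and the pipeline never pools
  studies before normalization.
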