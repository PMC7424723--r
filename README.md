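# sigscore

Single-sample gene-set scoring and biomarker evaluation for FSHD
transcriptomics.

## The problem

In facioscapulohumeral muscular dystrophy (FSHD), the causal transcription
factor DUX4 is expressed transiently and in rare cells, so its transcript is
an unreliable readout. The field instead summarizes each sample with
signature scores over DUX4 target-gene sets (early, ~8 h induction; late,
24–48 h), a PAX7 target repression contrast, and a lymphoblast-derived
up-regulated gene set, then asks how well each score separates cases from
controls — within a cell-line experiment, or pooled across heterogeneous
muscle-biopsy studies.

`sigscore` implements that pipeline end to end:

* **Scores** — mean expression of an unsigned set; within-sample Welch *t*
  contrasting a signed set's up genes against its down genes
  (score `t_j = (x̄_up − x̄_down) / √(s²_up/n_up + s²_down/n_down)` per sample `j`);
  transcript-detection calls (positive ⇔ normalized count > 0);
  z-normalization within matched pairs or studies.
* **Evaluation** — Wilcoxon rank-sum (exact or tie-corrected normal
  approximation), tie-aware ROC/AUC with `AUC = U/(n₁n₀)`, DeLong's paired
  AUC test via placement values.
* **Meta-analysis** — per-study mean z-score differences with Welch 95% CIs,
  DerSimonian–Laird random-effects pooling
  (`τ² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))`), Fisher's combined test
  (`X² = −2Σ log pᵢ` on 2k df), forest tables and plots.
* **Association** — Pearson score–score correlations; multivariate OLS of a
  score on histological and MRI disease-activity covariates.
* **Signature derivation** — per-gene covariate-adjusted OLS ranking on log2
  expression, top-k cut, positive-effect filter.
* **Synthetic data** — multi-study case/control cohorts with planted effects,
  matched-pair replicate designs with a leaky control line, and a single-cell
  transcription-burst model (factor decays, targets activate with delay),
  all deterministic given a seed.

Everything takes plain data frames / simple S3 objects and returns tibbles,
so results chain with the pipe; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

Simulate a seven-study biopsy-scale compendium (130 cases, 97 controls) with
a planted standardized score separation of 0.43 z-units on a 237-gene
signature, score it, and evaluate the signature as a biomarker:

```r
library(sigscore)

spec   <- cohort_spec(seed = 7)          # defaults: seven studies, delta = 0.43
cohort <- generate_cohort(spec)
sets   <- list(gene_set("lymphoblast_like", cohort$truth$signature_genes))
scores <- score_panel(cohort$expression, sets, cohort$samples, grouping = "study")

roc_auc(scores$z_score, scores$condition)
#> <roc_result> AUC = 0.6696 (n = 130 case, 97 control), Wilcoxon p = 1.25e-05

meta <- pool_random_effects(study_effects(scores))
meta
#> <meta_result> k = 7 studies; pooled = 0.611 [0.344, 0.878], tau2 = 0.0000
#>   Fisher combined: X2 = 35.483 on 14 df, p = 0.001246

tidy(meta)
#> # A tibble: 8 × 8
#>   label              estimate   ci_lo ci_hi       p stars crosses_zero is_pooled
#> 1 study1                0.497 -0.0596 1.05  0.0344  "*"   TRUE         FALSE
#> 2 study2                0.238 -0.522  0.998 0.534   ""    TRUE         FALSE
#> ...
#> 7 study7                1.11   0.495  1.72  0.00158 "**"  FALSE        FALSE
#> 8 Pooled (random ef…    0.611  0.344  0.878 0.00125 "**"  FALSE        TRUE
```

The pooled AUC of 0.67 here is one draw around the planted value
Φ(0.43/√2) ≈ 0.62: a weak-but-real biomarker. The forest table shows each
study's mean z-score difference with its 95% interval (stars: `*` p < 0.05,
`**` p < 0.01, `***` p < 0.001 from the per-study Wilcoxon test), and the
pooled random-effects row with Fisher's combined p. `autoplot(meta)` draws
the forest plot, `autoplot(roc_auc(...))` the ROC curve.

A command-line wrapper over the same functions is installed at
`system.file("cli", "sigscore", package = "sigscore")` with subcommands
`simulate`, `score`, `evaluate`, `meta`, `associate`, `derive`.

## Package layout

* `R/` — expression-matrix and gene-set I/O, normalization, scoring,
  derivation, evaluation, meta-analysis, association, synthetic generators,
  pipeline commands, plotting and tidier methods.
* `tests/testthat/` — unit and property tests per module plus end-to-end
  statistical acceptance checks (oracle equivalence, null calibration,
  parameter recovery, burst-pattern dissociation).
* `vignettes/signature-biomarkers.Rmd` — the models, their assumptions, the
  tunable parameters, and the design decisions, in detail.
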