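Package: sigscore
Title: Single-Sample Gene-Set Scoring and Biomarker Evaluation for FSHD
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes single-sample gene-set signature scores (mean-expression
    scores for unsigned sets, within-sample Welch t contrasts for signed sets)
    from bulk or single-cell expression matrices, calls DUX4 transcript
    positivity, z-normalizes scores within matched-pair groups or studies, and
    evaluates candidate biomarkers by Wilcoxon rank-sum tests, ROC/AUC analysis
    and DeLong's paired AUC comparison. Cross-study evidence is pooled with a
    DerSimonian-Laird random-effects meta-analysis and Fisher's combined
    probability test, and scores are related to disease-activity covariates via
    Pearson correlation and multivariate regression. Includes synthetic-data
    generators with known ground truth: multi-study case/control cohorts,
    matched-pair replicate designs, and a transient transcription-burst model
    for single-cell counts in which a factor's transcript decays while its
    target genes activate with delay.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    metafor,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
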