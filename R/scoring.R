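#' Mean-expression signature score
#'
#' The single-sample score for an unsigned gene set: the mean expression of
#' the set's genes present in the matrix, one value per sample. This is the
#' score used for the three DUX4 target-gene signatures (Choi 8 h, Geng 24 h,
#' Yao 24-48 h) and the 237-gene FSHD Lymphoblast set.
#'
#' Cross-platform data rarely carry every signature gene, so genes absent from
#' the matrix are dropped: below full coverage a warning lists them, and below
#' `min_fraction` coverage (default 0.5) an error is raised unless
#' `on_low_coverage = "warn"`.
#'
#' @param m An [expr_matrix].
#' @param s A [gene_set].
#' @param min_fraction Minimum fraction of signature genes that must be present.
#' @param on_low_coverage `"error"` (default) or `"warn"` when coverage falls
#'   below `min_fraction`.
#' @return Named numeric vector of per-sample scores, with the absent genes in
#'   attribute `"absent_genes"`.
#' @export
mean_signature_score <- function(m, s, min_fraction = 0.5,
                                 on_low_coverage = c("error", "warn")) {
  on_low_coverage <- match.arg(on_low_coverage)
  stopifnot(inherits(s, "gene_set"))
  present <- intersect(s$genes, rownames(m))
  absent <- setdiff(s$genes, rownames(m))
  if (length(present) == 0) {
    abort(paste0(
      "No genes of set '", s$name, "' found in the matrix; missing: ",
      toString(head(absent, 10)), if (length(absent) > 10) ", ..." else ""
    ))
  }
  frac <- length(present) / length(s$genes)
  if (frac < min_fraction) {
    msg <- sprintf(
      "Set '%s': only %d/%d genes present (%.0f%% < %.0f%% required).",
      s$name, length(present), length(s$genes), 100 * frac, 100 * min_fraction
    )
    if (on_low_coverage == "error") abort(msg) else warn(msg)
  } else if (length(absent) > 0) {
    warn(sprintf(
      "Set '%s': %d/%d genes absent from the matrix.",
      s$name, length(absent), length(s$genes)
    ))
  }
  scores <- colMeans(em_values(m)[present, , drop = FALSE])
  attr(scores, "absent_genes") <- absent
  scores
}

#' Within-sample up-vs-down contrast score
#'
#' The signed-set score: for each sample, the Welch (unequal-variance)
#' two-sample t statistic comparing the expression of the up-regulated genes
#' against the down-regulated genes within that sample. Positive scores mean
#' the up set sits higher. This is the PAX7 target-gene score construction
#' (311 up vs 290 down genes), where repression of PAX7 targets yields
#' negative scores in affected muscle.
#'
#' @param m An [expr_matrix].
#' @param s A [signed_gene_set]; at least 2 up and 2 down genes must be present
#'   in the matrix.
#' @return Named numeric vector of per-sample t scores.
#' @export
contrast_t_score <- function(m, s) {
  stopifnot(inherits(s, "signed_gene_set"))
  up <- intersect(s$up_genes, rownames(m))
  down <- intersect(s$down_genes, rownames(m))
  if (length(up) < 2 || length(down) < 2) {
    abort(sprintf(
      "Set '%s': need >=2 up and >=2 down genes present; found %d up, %d down.",
      s$name, length(up), length(down)
    ))
  }
  x <- em_values(m)
  vapply(colnames(x), function(j) {
    u <- x[up, j]
    d <- x[down, j]
    vu <- var(u)
    vd <- var(d)
    if (vu == 0 && vd == 0) {
      abort(sprintf(
        "Sample '%s': zero variance in both gene sets; contrast t undefined.", j
      ))
    }
    (mean(u) - mean(d)) / sqrt(vu / length(u) + vd / length(d))
  }, numeric(1))
}

#' Transcript-detection (DUX4 positivity) call
#'
#' A sample is called positive for the target transcript if any normalized
#' read is present, i.e. the normalized count exceeds zero. Normalization
#' rescales counts but cannot create signal from zero reads, so "> 0" is the
#' read-level detection rule applied to normalized data.
#'
#' @param m A linear-scale [expr_matrix] of normalized counts.
#' @param gene Target gene identifier (default `"DUX4"`).
#' @return Tibble with columns `sample_id`, `gene`, `normalized_count`,
#'   `positive`.
#' @export
dux4_positive <- function(m, gene = "DUX4") {
  if (expr_scale(m) != "linear") {
    abort("Detection calls need linear-scale normalized counts, not log2 values.")
  }
  if (!gene %in% rownames(m)) {
    abort(paste0("Gene '", gene, "' not present in the matrix."))
  }
  counts <- em_values(m)[gene, ]
  tibble::tibble(
    sample_id = names(counts),
    gene = gene,
    normalized_count = unname(counts),
    positive = unname(counts) > 0
  )
}

#' z-normalize scores within groups
#'
#' Centers and scales scores to mean 0, sd 1 (n-1 denominator) within each
#' group — the matched control pair for cell-line data, or the study for
#' biopsy cohorts — so that scores from heterogeneous platforms become
#' poolable.
#'
#' @param scores Named numeric vector of per-sample scores.
#' @param grouping Named character vector mapping each sample to its group, or
#'   a vector aligned with `scores`.
#' @return Numeric vector of z-scores, same names and order as `scores`.
#' @export
z_normalize <- function(scores, grouping) {
  if (!is.null(names(grouping)) && !is.null(names(scores))) {
    missing <- setdiff(names(scores), names(grouping))
    if (length(missing) > 0) {
      abort(paste0("No group for sample(s): ", toString(head(missing, 5))))
    }
    grouping <- grouping[names(scores)]
  }
  if (length(grouping) != length(scores)) {
    abort("`grouping` must cover every score.")
  }
  out <- scores
  for (g in unique(grouping)) {
    idx <- which(grouping == g)
    if (length(idx) < 2) {
      abort(paste0("Group '", g, "' has a single sample; cannot z-normalize."))
    }
    s <- sd(scores[idx])
    if (s == 0) {
      abort(paste0("Group '", g, "' has zero score variance; cannot z-normalize."))
    }
    out[idx] <- (scores[idx] - mean(scores[idx])) / s
  }
  out
}

#' Score a panel of signatures across a cohort
#'
#' Computes the raw score of every signature for every sample (unsigned sets
#' via [mean_signature_score()], signed sets via [contrast_t_score()]) and
#' z-normalizes within the chosen grouping: `"group"` (matched control pairs),
#' `"study"`, or `"none"` (z-scores equal raw scores).
#'
#' @param m An [expr_matrix].
#' @param sets List of [gene_set] / [signed_gene_set] objects.
#' @param meta Sample table covering every sample of `m`.
#' @param grouping `"group"`, `"study"` or `"none"`.
#' @param ... Passed to [mean_signature_score()] (e.g. `min_fraction`).
#' @return A tibble (one row per sample x signature) with columns `sample_id`,
#'   `signature`, `raw_score`, `z_score`, `group`, `study`, `condition`;
#'   attribute `"grouping"` records the normalization used.
#' @export
score_panel <- function(m, sets, meta, grouping = c("group", "study", "none"),
                        ...) {
  grouping <- match.arg(grouping)
  if (length(sets) == 0) abort("`sets` must contain at least one signature.")
  meta <- as_sample_table(meta)
  samples <- colnames(m)
  missing <- setdiff(samples, meta$sample_id)
  if (length(missing) > 0) {
    abort(paste0("Samples missing from metadata: ", toString(head(missing, 5))))
  }
  meta <- meta[match(samples, meta$sample_id), ]
  gmap <- switch(grouping,
    group = setNames(meta$group, meta$sample_id),
    study = setNames(meta$study, meta$sample_id),
    none = NULL
  )
  rows <- purrr::map(sets, function(s) {
    raw <- if (inherits(s, "signed_gene_set")) {
      contrast_t_score(m, s)
    } else {
      mean_signature_score(m, s, ...)
    }
    raw <- raw[samples]
    z <- if (is.null(gmap)) raw else z_normalize(raw, gmap)
    tibble::tibble(
      sample_id = samples,
      signature = s$name,
      raw_score = unname(raw),
      z_score = unname(z),
      group = meta$group,
      study = meta$study,
      condition = meta$condition
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "grouping") <- grouping
  out
}

#' Write / read a score table
#'
#' Long-format TSV with columns `sample_id`, `signature`, `raw_score`,
#' `z_score`, `group`, `study`, `condition`.
#'
#' @param scores A score tibble from [score_panel()].
#' @param path File path.
#' @return `path` (write) or the score tibble (read).
#' @export
write_scores <- function(scores, path) {
  readr::write_tsv(scores, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  readr::read_tsv(path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      signature = readr::col_character(),
      raw_score = readr::col_double(),
      z_score = readr::col_double(),
      .default = readr::col_character()
    ), progress = FALSE
  )
}
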