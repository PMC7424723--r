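#' Rank genes by covariate-adjusted case/control association
#'
#' Fits, per gene, an ordinary least-squares model of log2 expression on
#' condition plus sex and matched-pair (group) indicators, and ranks genes by
#' the Wald p-value of the condition coefficient. This is the
#' signature-derivation step: a covariate-adjusted per-gene ranking from which
#' the up-regulated signature is cut. A per-gene linear model on normalized
#' log2 values is used rather than a negative-binomial count model; the
#' procedure's shape (adjusted ranking, top-k, sign filter) is what the
#' downstream steps depend on.
#'
#' Columns of the design that are collinear (e.g. sex constant within
#' sex-matched pairs, hence aliased with the pair indicators) are dropped
#' automatically; if the condition column itself is aliased the design is
#' unusable and an error is raised.
#'
#' @param m A log2-scale [expr_matrix].
#' @param meta Sample table with `condition`, `sex`, `group` for all samples.
#' @return A tibble (class `gene_ranking`) with columns `gene_id`, `effect`
#'   (condition coefficient, log2 units, case minus control), `p_value`,
#'   `rank`; sorted by ascending p, ties broken by descending |effect| then
#'   gene_id.
#' @export
rank_genes <- function(m, meta) {
  if (expr_scale(m) != "log2") {
    abort("`m` must be on the log2 scale (see log_transform()).")
  }
  meta <- as_sample_table(meta)
  samples <- colnames(m)
  if (length(samples) < 2) abort("Need at least 2 samples to rank genes.")
  missing <- setdiff(samples, meta$sample_id)
  if (length(missing) > 0) {
    abort(paste0("Samples missing from metadata: ", toString(head(missing, 5))))
  }
  meta <- meta[match(samples, meta$sample_id), ]
  if (!"sex" %in% names(meta)) meta$sex <- "unknown"
  dat <- data.frame(
    condition = factor(meta$condition, levels = c("control", "case")),
    sex = factor(meta$sex),
    group = factor(meta$group)
  )
  X <- model.matrix(~ condition + sex + group, dat)
  cond_col <- which(colnames(X) == "conditioncase")
  if (qr(X)$rank == qr(X[, -cond_col, drop = FALSE])$rank) {
    abort("Design is rank-deficient in condition: condition is confounded with the covariates.")
  }
  # retain a full-rank column basis, never sacrificing the condition column
  keep <- c(1L, cond_col)
  for (j in setdiff(seq_len(ncol(X)), keep)) {
    if (qr(X[, c(keep, j), drop = FALSE])$rank > length(keep)) keep <- c(keep, j)
  }
  Xk <- X[, sort(keep), drop = FALSE]
  n <- nrow(Xk)
  p <- ncol(Xk)
  if (n <= p) {
    abort(sprintf(
      "Fewer samples (%d) than residual degrees of freedom allow (design has %d columns).",
      n, p
    ))
  }
  Y <- t(em_values(m)) # samples x genes
  fit <- lm.fit(Xk, Y)
  cond_idx <- which(colnames(Xk) == "conditioncase")
  beta <- fit$coefficients[cond_idx, ]
  df <- n - p
  sigma2 <- colSums(fit$residuals^2) / df
  xtx_inv <- chol2inv(chol(crossprod(Xk)))
  se <- sqrt(sigma2 * xtx_inv[cond_idx, cond_idx])
  tstat <- beta / se
  pval <- 2 * pt(-abs(tstat), df)
  # flat genes: zero residual variance and zero effect -> no evidence, p = 1
  degenerate <- se < .Machine$double.eps
  beta[degenerate & abs(beta) < .Machine$double.eps] <- 0
  pval[degenerate] <- ifelse(abs(beta[degenerate]) > 0, .Machine$double.xmin, 1)
  out <- tibble::tibble(
    gene_id = rownames(m),
    effect = unname(beta),
    p_value = unname(pval)
  )
  out <- dplyr::arrange(out, .data$p_value, dplyr::desc(abs(.data$effect)), .data$gene_id)
  out$rank <- seq_len(nrow(out))
  class(out) <- c("gene_ranking", class(out))
  out
}

#' Cut an up-regulated signature from a gene ranking
#'
#' Takes the `top_k` most significant genes (default 500) and keeps those with
#' a positive condition effect — the transcriptional-activator rationale:
#' genes suppressed by an activator add no power to its expression biomarkers,
#' so only the up-regulated side of the ranking is kept as the signature.
#'
#' @param r A `gene_ranking` from [rank_genes()].
#' @param top_k Number of top-ranked genes to consider.
#' @param name Name for the derived set.
#' @return A [gene_set] of the positive-effect genes among the top `top_k`,
#'   with attribute `"counts"` = `c(k_up, top_k)`. Empty result (all effects
#'   negative) yields a zero-gene set plus a warning.
#' @export
derive_up_signature <- function(r, top_k = 500, name = "derived_up") {
  if (!is.numeric(top_k) || top_k < 1) abort("`top_k` must be >= 1.")
  if (top_k > nrow(r)) {
    abort(sprintf("`top_k` (%d) exceeds the %d ranked genes.", top_k, nrow(r)))
  }
  top <- r[seq_len(top_k), ]
  up <- top$gene_id[top$effect > 0]
  if (length(up) == 0) {
    warn("No up-regulated genes among the top-ranked set; returning an empty set.")
    s <- structure(list(name = name, genes = character(0)), class = "gene_set")
  } else {
    s <- gene_set(name, up)
  }
  attr(s, "counts") <- c(k_up = length(up), top_k = as.integer(top_k))
  s
}

#' Write a gene ranking as TSV
#'
#' @param r A `gene_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(r, path) {
  readr::write_tsv(r, path, progress = FALSE)
  invisible(path)
}

#' p-value histogram of a gene ranking
#'
#' Diagnostic plot: under the null the p-values are uniform; an excess near 0
#' reflects genuine differential expression.
#'
#' @param r A `gene_ranking`.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_pvalue_histogram <- function(r, bins = 40) {
  ggplot2::ggplot(r, ggplot2::aes(x = .data$p_value)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey35") +
    ggplot2::labs(x = "p-value (condition coefficient)", y = "genes") +
    ggplot2::theme_minimal()
}
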