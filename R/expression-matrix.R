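#' Expression matrix container
#'
#' A genes x samples numeric matrix carrying a scale tag. `"linear"` marks
#' normalized counts or intensities (values must be non-negative); `"log2"`
#' marks log2-transformed values. The tag makes the state of each input
#' explicit so that downstream steps (log transformation, transcript-detection
#' calls) can refuse inputs on the wrong scale.
#'
#' @param values Numeric matrix with unique, non-empty rownames (gene
#'   identifiers) and colnames (sample identifiers).
#' @param scale `"linear"` or `"log2"`.
#' @return An object of class `expr_matrix`: the matrix with a `scale`
#'   attribute.
#' @examples
#' m <- expr_matrix(matrix(1:6, 3, 2,
#'   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))), scale = "linear")
#' expr_scale(m)
#' @export
expr_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort("`values` must have rownames (genes) and colnames (samples).")
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g) > 0) {
    abort(paste0("Duplicate gene identifiers: ", toString(head(dup_g, 5))))
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0) {
    abort(paste0("Duplicate sample identifiers: ", toString(head(dup_s, 5))))
  }
  if (any(!is.finite(values))) {
    abort("Expression values must all be finite.")
  }
  if (scale == "linear" && any(values < 0)) {
    abort("Negative values are not allowed on the linear scale.")
  }
  structure(values, scale = scale, class = c("expr_matrix", "matrix", "array"))
}

#' @rdname expr_matrix
#' @param m An `expr_matrix`.
#' @export
expr_scale <- function(m) {
  attr(m, "scale") %||% "linear"
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d samples, scale = %s\n",
    nrow(x), ncol(x), expr_scale(x)
  ))
  print(head(unclass(x)[, seq_len(min(ncol(x), 6)), drop = FALSE], 5))
  invisible(x)
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- unclass(x)[i, j, ..., drop = drop]
  if (is.matrix(out)) {
    structure(out,
      scale = expr_scale(x),
      class = c("expr_matrix", "matrix", "array")
    )
  } else {
    out
  }
}

em_values <- function(m) {
  structure(unclass(m), scale = NULL)
}

#' Read an expression matrix from TSV
#'
#' Expects tab-separated text with a header row of sample identifiers and the
#' gene identifier in the first column (conventionally named `gene_id`).
#'
#' @param path File path.
#' @param scale Scale tag to attach: `"linear"` (default) or `"log2"`. Inputs
#'   downloaded already log-transformed should be tagged `"log2"` so they are
#'   not transformed twice.
#' @return An [expr_matrix].
#' @export
read_expression_matrix <- function(path, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      .default = readr::col_character()
    ), progress = FALSE
  )
  if (ncol(df) < 2) {
    abort(paste0("Malformed header in ", path, ": need gene column + samples"))
  }
  gene_ids <- df[[1]]
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate gene rows in ", path, ": ", toString(head(dup, 5))))
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    abort(sprintf(
      "Non-numeric or non-finite value '%s' at gene '%s' (row %d), sample '%s' (column %d)",
      vals[b[1], b[2]], gene_ids[b[1]], b[1], colnames(vals)[b[2]], b[2] + 1L
    ))
  }
  dimnames(num) <- list(gene_ids, colnames(vals))
  expr_matrix(num, scale = scale)
}

#' Write an expression matrix as TSV
#'
#' Values are written with 10 significant digits, enough for round-tripping
#' scores and simulated data through the text formats the readers accept.
#'
#' @param m An [expr_matrix].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- tibble::as_tibble(em_values(m), rownames = "gene_id")
  num_cols <- setdiff(names(df), "gene_id")
  for (cl in num_cols) df[[cl]] <- sprintf("%.10g", df[[cl]])
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Log-transform a linear-scale expression matrix
#'
#' Applies `log2(x + pseudocount)` and retags the matrix as log2 scale, the
#' first half of the within-study log + quantile normalization applied to each
#' downloaded cohort before scoring.
#'
#' @param m An [expr_matrix] on the linear scale.
#' @param pseudocount Positive offset added before the logarithm; default 1, so
#'   zero counts map to zero.
#' @return A log2-scale [expr_matrix].
#' @export
log_transform <- function(m, pseudocount = 1) {
  if (expr_scale(m) != "linear") {
    abort("`m` is already on the log2 scale; refusing to log-transform twice.")
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    abort("`pseudocount` must be a single positive number.")
  }
  expr_matrix(log2(em_values(m) + pseudocount), scale = "log2")
}

#' Within-study log + quantile normalization
#'
#' Applies the standard preprocessing to a multi-study matrix: samples are
#' split by study and each study is log-transformed (if the matrix is on the
#' linear scale) and quantile-normalized independently — normalization is
#' strictly within study, never pooled across studies.
#'
#' @param m An [expr_matrix].
#' @param meta Sample table assigning each sample to a study.
#' @param log Apply [log_transform()] first (skipped automatically for
#'   log2-tagged input).
#' @param quantile Apply [quantile_normalize()] per study.
#' @param pseudocount Passed to [log_transform()].
#' @return A log2-scale [expr_matrix] with the original sample order.
#' @export
normalize_within_study <- function(m, meta, log = TRUE, quantile = TRUE,
                                   pseudocount = 1) {
  meta <- as_sample_table(meta)
  samples <- colnames(m)
  missing <- setdiff(samples, meta$sample_id)
  if (length(missing) > 0) {
    abort(paste0("Samples missing from metadata: ", toString(head(missing, 5))))
  }
  study_of <- meta$study[match(samples, meta$sample_id)]
  pieces <- lapply(unique(study_of), function(st) {
    sub <- m[, samples[study_of == st], drop = FALSE]
    if (log && expr_scale(sub) == "linear") {
      sub <- log_transform(sub, pseudocount = pseudocount)
    }
    if (quantile) sub <- quantile_normalize(sub)
    sub
  })
  out <- do.call(cbind, lapply(pieces, em_values))
  out <- out[, samples, drop = FALSE]
  expr_matrix(out, scale = if (log) "log2" else expr_scale(m))
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution: the
#' across-sample mean of sorted value vectors. Ties within a sample receive the
#' mean of the reference values at their tied ranks, so within-sample rank
#' order is preserved. Normalization is a within-study operation: matrices from
#' different studies must be normalized independently, never pooled.
#'
#' @param m An [expr_matrix] with at least 2 samples.
#' @return An [expr_matrix] on the same scale.
#' @export
quantile_normalize <- function(m) {
  x <- em_values(m)
  if (ncol(x) < 2) {
    abort("Quantile normalization needs at least 2 samples.")
  }
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    v <- ref[rank(col, ties.method = "first")]
    ave(v, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(x)
  expr_matrix(out, scale = expr_scale(m))
}
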