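#' Pairwise Pearson correlations between signature scores
#'
#' Correlates every unordered pair of signatures across samples, on the
#' z-normalized scores (correlation after within-study normalization is what
#' makes cross-platform pooling meaningful). p-values come from the
#' t-distribution test of Pearson's r. Pairs involving a constant score
#' vector (undefined r) are skipped with a warning.
#'
#' @param scores Score tibble from [score_panel()].
#' @param subset Optional character vector of signature names to restrict to.
#' @param use Score column: `"z_score"` (default) or `"raw_score"`.
#' @return Tibble: `signature_a`, `signature_b`, `r`, `p`, `n`.
#' @export
correlation_matrix <- function(scores, subset = NULL,
                               use = c("z_score", "raw_score")) {
  use <- match.arg(use)
  wide <- tidyr::pivot_wider(
    dplyr::select(scores, "sample_id", "signature", dplyr::all_of(use)),
    names_from = "signature", values_from = dplyr::all_of(use)
  )
  sigs <- setdiff(names(wide), "sample_id")
  if (!is.null(subset)) {
    missing <- setdiff(subset, sigs)
    if (length(missing) > 0) {
      abort(paste0("Signature(s) not in the score table: ", toString(missing)))
    }
    sigs <- subset
  }
  if (length(sigs) < 2) abort("Need at least two signatures to correlate.")
  pairs <- combn(sigs, 2, simplify = FALSE)
  rows <- purrr::map(pairs, function(pr) {
    a <- wide[[pr[1]]]
    b <- wide[[pr[2]]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 3) {
      warn(paste0("Pair ", pr[1], " / ", pr[2], ": fewer than 3 complete samples; skipped."))
      return(NULL)
    }
    if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
      warn(paste0("Pair ", pr[1], " / ", pr[2], ": constant score vector; skipped."))
      return(NULL)
    }
    ct <- cor.test(a[ok], b[ok], method = "pearson")
    tibble::tibble(
      signature_a = pr[1], signature_b = pr[2],
      r = unname(ct$estimate), p = ct$p.value, n = sum(ok)
    )
  })
  dplyr::bind_rows(rows)
}

#' Multivariate association of a score with disease-activity covariates
#'
#' Ordinary least-squares regression of one signature score on all supplied
#' covariates simultaneously (with intercept), reporting each covariate's
#' coefficient, t-value and two-sided p — the "independent association"
#' analysis relating scores to histological (pathology score, inflammation,
#' active disease) and MRI-based (STIR, T1, fat fraction) measures. Rows with
#' any missing covariate or score are dropped (listwise deletion).
#'
#' @param score Named (by sample) or plain numeric vector of scores.
#' @param covariates Data frame of numeric covariate columns, rows aligned
#'   with `score`.
#' @param response_name Label for the response in the output.
#' @return Tibble (one row per covariate): `response`, `term`, `estimate`,
#'   `t_value`, `p`; attributes `n_used` and `n_dropped`.
#' @export
multivariate_association <- function(score, covariates,
                                     response_name = "score") {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(score)) {
    abort("`covariates` must have one row per score.")
  }
  non_num <- names(covariates)[!vapply(covariates, is.numeric, logical(1))]
  if (length(non_num) > 0) {
    abort(paste0("Non-numeric covariate column(s): ", toString(non_num)))
  }
  dat <- cbind(data.frame(.score = as.numeric(score)), covariates)
  ok <- complete.cases(dat)
  n_used <- sum(ok)
  if (n_used < ncol(covariates) + 2) {
    abort(sprintf(
      "Only %d complete-case samples for %d covariates; need at least %d.",
      n_used, ncol(covariates), ncol(covariates) + 2
    ))
  }
  dat <- dat[ok, , drop = FALSE]
  X <- model.matrix(~., data = dat[, -1, drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    partners <- unique(unlist(lapply(dropped, function(d) {
      cf <- qr.coef(qr(X[, setdiff(colnames(X), c(d, "(Intercept)")), drop = FALSE]), X[, d])
      names(cf)[which(abs(cf) > 1e-8)]
    })))
    abort(paste0(
      "Design is rank-deficient: collinear covariate(s) ",
      toString(unique(c(dropped, partners)))
    ))
  }
  fit <- lm(.score ~ ., data = dat)
  sm <- summary(fit)$coefficients
  terms <- setdiff(rownames(sm), "(Intercept)")
  out <- tibble::tibble(
    response = response_name,
    term = terms,
    estimate = unname(sm[terms, "Estimate"]),
    t_value = unname(sm[terms, "t value"]),
    p = unname(sm[terms, "Pr(>|t|)"])
  )
  attr(out, "n_used") <- n_used
  attr(out, "n_dropped") <- length(score) - n_used
  out
}

#' Regress every signature on the disease-activity covariates
#'
#' Applies [multivariate_association()] to each signature of a score table,
#' pulling covariates from the sample table. By default p-values are reported
#' per response without multiplicity correction, matching per-score reporting;
#' `adjust = "BH"` applies Benjamini-Hochberg within each response.
#'
#' @param scores Score tibble from [score_panel()].
#' @param meta Sample table carrying covariate columns.
#' @param covariates Covariate column names; default [covariate_names()] of
#'   `meta`.
#' @param use Score column: `"z_score"` (default) or `"raw_score"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Tibble of per-covariate results, stacked over responses.
#' @export
associate_covariates <- function(scores, meta, covariates = NULL,
                                 use = c("z_score", "raw_score"),
                                 adjust = c("none", "BH")) {
  use <- match.arg(use)
  adjust <- match.arg(adjust)
  meta <- as_sample_table(meta)
  covariates <- covariates %||% covariate_names(meta)
  if (length(covariates) == 0) abort("No covariate columns found.")
  missing <- setdiff(covariates, names(meta))
  if (length(missing) > 0) {
    abort(paste0("Covariate(s) not in the sample table: ", toString(missing)))
  }
  out <- scores |>
    dplyr::group_by(.data$signature) |>
    dplyr::group_map(function(d, key) {
      idx <- match(d$sample_id, meta$sample_id)
      res <- multivariate_association(
        d[[use]], meta[idx, covariates, drop = FALSE],
        response_name = key$signature
      )
      res$n_used <- attr(res, "n_used")
      res
    }) |>
    dplyr::bind_rows()
  if (adjust == "BH") {
    out <- out |>
      dplyr::group_by(.data$response) |>
      dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = "BH")) |>
      dplyr::ungroup()
  }
  out
}
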