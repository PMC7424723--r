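#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Computes U from midranks (ties contribute half) and a two-sided p-value.
#' Mode `"auto"` uses exact enumeration when the combined sample size is at
#' most 12 and there are no ties, otherwise the normal approximation with
#' tie-corrected variance and continuity correction. U counts case-over-control
#' pairs, so `U / (n_x * n_y)` is the tie-aware AUC of `x` against `y`.
#'
#' @param x,y Numeric score vectors (x = cases, y = controls).
#' @param mode `"auto"`, `"exact"` or `"approx"`.
#' @return List with `U`, `p`, and the `method` used.
#' @export
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) {
    abort("Both score vectors must be non-empty.")
  }
  nx <- length(x)
  ny <- length(y)
  all_v <- c(x, y)
  r <- rank(all_v)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(all_v) > 0
  if (mode == "exact" && ties) {
    abort("Exact mode requires tie-free data; use mode = 'approx' or 'auto'.")
  }
  use_exact <- switch(mode,
    exact = TRUE,
    approx = FALSE,
    auto = !ties && (nx + ny) <= 12
  )
  if (use_exact) {
    p <- if (U > nx * ny / 2) {
      2 * (1 - pwilcox(U - 1, nx, ny))
    } else {
      2 * pwilcox(U, nx, ny)
    }
    p <- min(1, p)
    method <- "exact"
  } else {
    mu <- nx * ny / 2
    tab <- table(all_v)
    n <- nx + ny
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(tab^3 - tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      # all values tied: no information against the null
      return(list(U = U, p = 1, method = "approx"))
    }
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "approx"
  }
  list(U = U, p = p, method = method)
}

#' ROC curve and AUC for a case/control score
#'
#' The positive class is `"case"` and higher scores are treated as more
#' case-like; a signature expected to fall in cases is evaluated without sign
#' flip and simply reports AUC < 0.5. AUC is computed from midranks, so
#' `AUC = U / (n_case * n_control)` with ties contributing one half, and the
#' curve traces sensitivity (TPR) against 1 - specificity (FPR) over every
#' threshold.
#'
#' @param scores Numeric score vector.
#' @param labels Vector of `"case"`/`"control"` labels (or a factor/logical
#'   where `TRUE` means case), aligned with `scores`.
#' @return An object of class `roc_result`: list with `auc`, `curve` (tibble
#'   of `threshold`, `fpr`, `tpr`), `n_case`, `n_control`, `U`, `p`
#'   (two-sided Wilcoxon).
#' @export
roc_auc <- function(scores, labels) {
  lab <- normalize_labels(labels)
  if (length(lab) != length(scores)) {
    abort("`scores` and `labels` must have equal length.")
  }
  x <- scores[lab == "case"]
  y <- scores[lab == "control"]
  if (length(x) == 0 || length(y) == 0) {
    abort("Both classes must be present to compute a ROC curve.")
  }
  w <- wilcoxon_rank_sum(x, y, mode = "auto")
  auc <- w$U / (length(x) * length(y))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- tibble::tibble(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(y >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(x >= t), numeric(1))
  )
  structure(
    list(
      auc = auc, curve = curve, n_case = length(x), n_control = length(y),
      U = w$U, p = w$p
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.4f (n = %d case, %d control), Wilcoxon p = %.3g\n",
    x$auc, x$n_case, x$n_control, x$p
  ))
  invisible(x)
}

#' DeLong's test for two paired AUCs
#'
#' Compares the AUCs of two score vectors measured on the same samples with
#' the same labels, using the structural-component (placement-value)
#' decomposition: per-case and per-control placements give the variances of
#' and covariance between the two empirical AUCs, from which a covariance-aware
#' z statistic and two-sided p are formed.
#'
#' @param scores_a,scores_b Numeric score vectors on the same samples.
#' @param labels Case/control labels shared by both.
#' @return List with `auc_a`, `auc_b`, `z`, `p`, `var_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  lab <- normalize_labels(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(lab)) {
    abort("`scores_a`, `scores_b` and `labels` must describe the same samples.")
  }
  case <- lab == "case"
  if (!any(case) || !any(!case)) {
    abort("Both classes must be present.")
  }
  placements <- function(s) {
    x <- s[case]
    y <- s[!case]
    m <- length(x)
    n <- length(y)
    # V10[i] = Pr over controls that case i places above; V01[j] symmetric
    v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
    v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
    list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
  }
  pa <- placements(scores_a)
  pb <- placements(scores_b)
  m <- pa$m
  n <- pa$n
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    z <- if (abs(d) <= .Machine$double.eps) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
  }
  p <- if (is.infinite(z)) 0 else min(1, 2 * pnorm(-abs(z)))
  list(auc_a = pa$auc, auc_b = pb$auc, z = z, p = p, var_diff = var_diff)
}

#' Evaluate every signature of a score table as a biomarker
#'
#' Runs [roc_auc()] on the z-normalized score of each signature, pooling all
#' samples present (z-normalization within group/study is what makes pooling
#' across heterogeneous studies meaningful).
#'
#' @param scores Score tibble from [score_panel()].
#' @param use Score column to evaluate: `"z_score"` (default) or `"raw_score"`.
#' @return Tibble with one row per signature: `signature`, `auc`, `U`, `p`,
#'   `n_case`, `n_control`; the `roc_result` objects in a list-column `roc`.
#' @export
evaluate_scores <- function(scores, use = c("z_score", "raw_score")) {
  use <- match.arg(use)
  scores |>
    dplyr::group_by(.data$signature) |>
    dplyr::group_map(function(d, key) {
      r <- roc_auc(d[[use]], d$condition)
      tibble::tibble(
        signature = key$signature,
        auc = r$auc, U = r$U, p = r$p,
        n_case = r$n_case, n_control = r$n_control,
        roc = list(r)
      )
    }) |>
    dplyr::bind_rows()
}

normalize_labels <- function(labels) {
  if (is.logical(labels)) {
    return(ifelse(labels, "case", "control"))
  }
  lab <- as.character(labels)
  bad <- setdiff(unique(lab), c("case", "control"))
  if (length(bad) > 0) {
    abort(paste0("Labels must be 'case'/'control'; found: ", toString(bad)))
  }
  lab
}
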