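#' Per-study case/control effect on a normalized score
#'
#' The forest-plot ingredient: the mean difference in z-normalized score
#' between cases and controls within one study, its Welch-t 95% confidence
#' interval, and the two-sided Wilcoxon rank-sum p-value. The sampling
#' variance fed to the random-effects pooling is recovered from the CI
#' half-width (divided by 1.96, squared).
#'
#' @param scores Numeric vector of (z-normalized) scores for one study.
#' @param labels Case/control labels aligned with `scores`.
#' @param study_id Study identifier.
#' @param conf_level Confidence level for the Welch interval.
#' @return One-row tibble: `study`, `estimate` (case minus control), `ci_lo`,
#'   `ci_hi`, `variance`, `p`, `n_case`, `n_control`.
#' @export
study_effect <- function(scores, labels, study_id, conf_level = 0.95) {
  lab <- normalize_labels(labels)
  x <- scores[lab == "case"]
  y <- scores[lab == "control"]
  if (length(x) < 2 || length(y) < 2) {
    abort(paste0(
      "Study '", study_id, "' needs >=2 samples in each class (found ",
      length(x), " case, ", length(y), " control)."
    ))
  }
  tt <- t.test(x, y, conf.level = conf_level)
  w <- wilcoxon_rank_sum(x, y)
  est <- mean(x) - mean(y)
  half <- diff(tt$conf.int) / 2
  tibble::tibble(
    study = study_id,
    estimate = est,
    ci_lo = tt$conf.int[1],
    ci_hi = tt$conf.int[2],
    variance = (half / qnorm(0.975))^2,
    p = w$p,
    n_case = length(x),
    n_control = length(y)
  )
}

#' Per-study effects for one signature across a cohort
#'
#' Convenience wrapper applying [study_effect()] to each study of a score
#' table.
#'
#' @param scores Score tibble from [score_panel()] (one signature, or filtered
#'   to one via `signature`).
#' @param signature Signature name to use when `scores` holds several.
#' @param use Score column: `"z_score"` (default) or `"raw_score"`.
#' @return Tibble of study effects, one row per study.
#' @export
study_effects <- function(scores, signature = NULL, use = c("z_score", "raw_score")) {
  use <- match.arg(use)
  if (!is.null(signature)) {
    scores <- dplyr::filter(scores, .data$signature == !!signature)
  }
  if (dplyr::n_distinct(scores$signature) != 1) {
    abort("`scores` must hold exactly one signature; use the `signature` argument.")
  }
  scores |>
    dplyr::group_by(.data$study) |>
    dplyr::group_map(function(d, key) {
      study_effect(d[[use]], d$condition, key$study)
    }) |>
    dplyr::bind_rows()
}

#' Random-effects pooling of study effects
#'
#' DerSimonian-Laird random-effects meta-analysis: the between-study variance
#' is `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w_i = 1/v_i`, and the pooled estimate uses weights
#' `1/(v_i + tau2)` with a normal-theory confidence interval. Overall
#' significance combines the per-study two-sided Wilcoxon p-values with
#' Fisher's method.
#'
#' @param effects Tibble of study effects from [study_effect()]/[study_effects()].
#' @param conf_level Confidence level of the pooled interval.
#' @return An object of class `meta_result`: list with `studies`, `pooled`,
#'   `ci_lo`, `ci_hi`, `tau2`, `Q`, `fisher_x2`, `fisher_p`, `k`.
#' @export
pool_random_effects <- function(effects, conf_level = 0.95) {
  k <- nrow(effects)
  if (is.null(k) || k < 1) abort("Need at least one study effect.")
  v <- effects$variance
  if (any(!is.finite(v)) || any(v <= 0)) {
    abort("Every study effect needs a finite positive variance.")
  }
  yi <- effects$estimate
  w <- 1 / v
  fe <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - fe)^2)
  tau2 <- if (k > 1) {
    max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  } else {
    0
  }
  wr <- 1 / (v + tau2)
  pooled <- sum(wr * yi) / sum(wr)
  se <- sqrt(1 / sum(wr))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  fc <- fisher_combined(effects$p)
  structure(
    list(
      studies = effects,
      pooled = pooled,
      ci_lo = pooled - zq * se,
      ci_hi = pooled + zq * se,
      se = se,
      tau2 = tau2,
      Q = Q,
      fisher_x2 = fc$x2,
      fisher_p = fc$p,
      k = k
    ),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "<meta_result> k = %d studies; pooled = %.3f [%.3f, %.3f], tau2 = %.4f\n",
    x$k, x$pooled, x$ci_lo, x$ci_hi, x$tau2
  ))
  cat(sprintf(
    "  Fisher combined: X2 = %.3f on %d df, p = %.4g\n",
    x$fisher_x2, 2 * x$k, x$fisher_p
  ))
  invisible(x)
}

#' Fisher's combined probability test
#'
#' `X2 = -2 * sum(log(p_i))`, referred to a chi-square distribution with `2k`
#' degrees of freedom.
#'
#' @param p_values Vector of p-values, each in (0, 1].
#' @return List with `x2`, `p`, `df`.
#' @export
fisher_combined <- function(p_values) {
  if (length(p_values) < 1) abort("Need at least one p-value.")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("All p-values must lie in (0, 1].")
  }
  x2 <- -2 * sum(log(p_values))
  df <- 2 * length(p_values)
  list(x2 = x2, p = pchisq(x2, df = df, lower.tail = FALSE), df = df)
}

#' Forest-plot table of a meta-analysis
#'
#' One row per study plus a pooled diamond row, with significance stars from
#' the per-study Wilcoxon p (`*` p < 0.05, `**` p < 0.01, `***` p < 0.001) and
#' a flag for intervals crossing zero (studies whose whiskers cross the zero
#' line have not attained significance).
#'
#' @param meta A `meta_result`.
#' @return Tibble: `label`, `estimate`, `ci_lo`, `ci_hi`, `p`, `stars`,
#'   `crosses_zero`, `is_pooled`.
#' @export
forest_table <- function(meta) {
  stopifnot(inherits(meta, "meta_result"))
  st <- meta$studies
  rows <- tibble::tibble(
    label = st$study,
    estimate = st$estimate,
    ci_lo = st$ci_lo,
    ci_hi = st$ci_hi,
    p = st$p,
    stars = significance_stars(st$p),
    crosses_zero = st$ci_lo <= 0 & st$ci_hi >= 0,
    is_pooled = FALSE
  )
  pooled <- tibble::tibble(
    label = "Pooled (random effects)",
    estimate = meta$pooled,
    ci_lo = meta$ci_lo,
    ci_hi = meta$ci_hi,
    p = meta$fisher_p,
    stars = significance_stars(meta$fisher_p),
    crosses_zero = meta$ci_lo <= 0 & meta$ci_hi >= 0,
    is_pooled = TRUE
  )
  dplyr::bind_rows(rows, pooled)
}

significance_stars <- function(p) {
  dplyr::case_when(
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Tidiers for meta-analysis results
#'
#' `tidy()` returns the forest table (per-study rows plus the pooled row);
#' `glance()` returns the one-row summary (pooled estimate, CI, tau2, Q,
#' Fisher combined statistic and p, k).
#'
#' @param x A `meta_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) {
  forest_table(x)
}

#' @rdname tidy.meta_result
#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(
    pooled = x$pooled, ci_lo = x$ci_lo, ci_hi = x$ci_hi, se = x$se,
    tau2 = x$tau2, Q = x$Q, fisher_x2 = x$fisher_x2, fisher_p = x$fisher_p,
    k = x$k
  )
}

#' Tidiers for ROC results
#'
#' `tidy()` returns the ROC curve points; `glance()` the one-row summary.
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy roc_result
#' @export
tidy.roc_result <- function(x, ...) {
  x$curve
}

#' @rdname tidy.roc_result
#' @method glance roc_result
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(
    auc = x$auc, U = x$U, p = x$p, n_case = x$n_case, n_control = x$n_control
  )
}
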