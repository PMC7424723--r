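#' Plot a ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False-positive rate (1 - specificity)",
      y = "True-positive rate (sensitivity)",
      title = sprintf(
        "AUC = %.3f (Wilcoxon p = %.2g; %d case vs %d control)",
        object$auc, object$p, object$n_case, object$n_control
      )
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of a meta-analysis
#'
#' Per-study mean score differences with 95% whiskers and the pooled
#' random-effects diamond; studies whose whiskers cross the zero line have not
#' attained significance.
#'
#' @param object A `meta_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot meta_result
#' @export
autoplot.meta_result <- function(object, ...) {
  ft <- forest_table(object)
  ft$label <- factor(ft$label, levels = rev(ft$label))
  ggplot2::ggplot(ft, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
      height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$is_pooled, size = .data$is_pooled)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 15, `TRUE` = 18), guide = "none") +
    ggplot2::scale_size_manual(values = c(`FALSE` = 2.5, `TRUE` = 4), guide = "none") +
    ggplot2::geom_text(
      ggplot2::aes(label = .data$stars),
      nudge_y = 0.25, size = 3.5
    ) +
    ggplot2::labs(
      x = "Mean score difference (case - control, z-units)", y = NULL,
      title = sprintf("Fisher combined p = %.2g", object$fisher_p)
    ) +
    ggplot2::theme_minimal()
}

#' Scatter-matrix of signature score pairs
#'
#' One panel per unordered pair of signatures, samples coloured by condition;
#' annotation gives Pearson's r for the panel.
#'
#' @param scores Score tibble from [score_panel()].
#' @param subset Optional signature names to restrict to.
#' @param use Score column: `"z_score"` (default) or `"raw_score"`.
#' @return A ggplot object (faceted by pair).
#' @export
plot_score_pairs <- function(scores, subset = NULL,
                             use = c("z_score", "raw_score")) {
  use <- match.arg(use)
  wide <- tidyr::pivot_wider(
    dplyr::select(scores, "sample_id", "condition", "signature", dplyr::all_of(use)),
    names_from = "signature", values_from = dplyr::all_of(use)
  )
  sigs <- setdiff(names(wide), c("sample_id", "condition"))
  if (!is.null(subset)) sigs <- intersect(subset, sigs)
  if (length(sigs) < 2) abort("Need at least two signatures to plot pairs.")
  pairs <- combn(sigs, 2, simplify = FALSE)
  long <- purrr::map(pairs, function(pr) {
    tibble::tibble(
      pair = paste(pr[1], "vs", pr[2]),
      x = wide[[pr[1]]],
      y = wide[[pr[2]]],
      condition = wide$condition
    )
  }) |> dplyr::bind_rows()
  ann <- long |>
    dplyr::group_by(.data$pair) |>
    dplyr::summarise(
      r = stats::cor(.data$x, .data$y),
      .groups = "drop"
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$condition), size = 1, alpha = 0.7) +
    ggplot2::geom_text(
      data = ann, inherit.aes = FALSE,
      ggplot2::aes(label = sprintf("r = %.2f", .data$r)),
      x = Inf, y = -Inf, hjust = 1.1, vjust = -0.6, size = 3
    ) +
    ggplot2::scale_colour_manual(values = c(case = "firebrick", control = "black")) +
    ggplot2::facet_wrap(~pair, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
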