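#' Specification for a multi-study case/control cohort
#'
#' Describes the simulated analogue of a multi-study muscle-biopsy compendium:
#' per-study case/control sample counts, a gene universe with a designated
#' signature whose genes carry a planted case-wise mean shift, study-specific
#' baseline offsets, a per-sample random intercept shared across genes
#' (variation that does not average away over a signature) and residual
#' Gaussian noise, all on the log2 scale.
#'
#' The defaults mirror the seven-study biopsy compendium analysed here: study
#' sizes 50, 30, 15, 49, 18, 22 and 43 samples (130 cases, 97 controls in
#' total; per-study splits are the generator's choice since only totals are
#' published), a 237-gene signature in a 2000-gene universe, and a planted
#' standardized score separation `target_delta` of 0.43 z-units — the
#' separation at which the pooled AUC of a mean score sits near 0.62 via
#' `AUC = pnorm(delta / sqrt(2))`.
#'
#' Either supply the per-gene effect `beta` (log2 units) directly, or supply
#' `target_delta` and let the spec solve for `beta`: for an m-gene mean score
#' the marginal between-sample score standard deviation within a study is
#' `sqrt(sigma_pair^2 + sigma^2 / m)`, so `beta = target_delta * sqrt(...)`.
#'
#' @param n_case,n_control Integer vectors of per-study arm sizes (equal
#'   length, each arm >= 2).
#' @param n_genes Size of the gene universe.
#' @param signature_size Number of signature (effect-carrying) genes.
#' @param target_delta Planted standardized score separation in z-units;
#'   ignored when `beta` is given.
#' @param beta Per-gene case effect in log2 units, or `NULL` to derive it from
#'   `target_delta`.
#' @param sigma Residual standard deviation (log2 units).
#' @param sigma_pair Standard deviation of the per-sample intercept shared
#'   across genes.
#' @param sigma_study Standard deviation of the per-study baseline offset
#'   (drawn at generation time unless `study_offsets` is given).
#' @param study_offsets Optional fixed per-study offsets.
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_case = c(25, 15, 10, 26, 10, 14, 30),
                        n_control = c(25, 15, 5, 23, 8, 8, 13),
                        n_genes = 2000,
                        signature_size = 237,
                        target_delta = 0.43,
                        beta = NULL,
                        sigma = 1,
                        sigma_pair = 0.5,
                        sigma_study = 1,
                        study_offsets = NULL,
                        seed = 1) {
  if (length(n_case) != length(n_control)) {
    abort("`n_case` and `n_control` must have one entry per study.")
  }
  if (any(n_case < 2) || any(n_control < 2)) {
    abort("Every study needs at least 2 samples per arm.")
  }
  if (signature_size < 1 || signature_size > n_genes) {
    abort("`signature_size` must lie in [1, n_genes].")
  }
  if (any(c(sigma, sigma_pair, sigma_study) < 0)) {
    abort("All standard deviations must be non-negative.")
  }
  if (!is.null(study_offsets) && length(study_offsets) != length(n_case)) {
    abort("`study_offsets` must have one entry per study.")
  }
  score_sd <- sqrt(sigma_pair^2 + sigma^2 / signature_size)
  if (is.null(beta)) {
    if (is.null(target_delta)) abort("Give either `beta` or `target_delta`.")
    beta <- target_delta * score_sd
  } else {
    target_delta <- beta / score_sd
  }
  structure(
    list(
      n_case = as.integer(n_case), n_control = as.integer(n_control),
      n_genes = as.integer(n_genes),
      signature_genes = sprintf("SIG%04d", seq_len(signature_size)),
      beta = beta, target_delta = target_delta,
      sigma = sigma, sigma_pair = sigma_pair, sigma_study = sigma_study,
      study_offsets = study_offsets, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate a multi-study case/control cohort
#'
#' Draws, on the log2 scale,
#' `x[g, j] = mu_g + study_offset + sample_intercept + beta * case * sig(g) + N(0, sigma)`
#' for every gene and sample of a [cohort_spec]. The sample intercept
#' (`sigma_pair`) is shared across all genes of a sample — the biological and
#' technical variation that does not average away over a signature — and is
#' drawn independently per biopsy: unlike the cell-line replicate design
#' ([generate_paired_replicates()]) the biopsy cohorts carry no case/control
#' matching, so cases and controls within a study stay exchangeable under the
#' null and the `group` column simply equals the study.
#'
#' @param spec A [cohort_spec].
#' @return List with `expression` (log2-scale [expr_matrix]), `samples`
#'   (sample table), and `truth` (planted delta, beta, signature genes,
#'   realized study offsets).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  k <- length(spec$n_case)
  offsets <- spec$study_offsets %||% rnorm(k, 0, spec$sigma_study)
  studies <- sprintf("study%d", seq_len(k))
  meta <- purrr::map2(seq_len(k), studies, function(i, st) {
    nc <- spec$n_case[i]
    nn <- spec$n_control[i]
    tibble::tibble(
      sample_id = c(
        sprintf("%s_case%02d", st, seq_len(nc)),
        sprintf("%s_ctrl%02d", st, seq_len(nn))
      ),
      condition = rep(c("case", "control"), c(nc, nn)),
      study = st,
      group = st,
      sex = "unknown",
      cell_type = "biopsy"
    )
  }) |> dplyr::bind_rows()
  n <- nrow(meta)
  g <- spec$n_genes
  gene_ids <- sprintf("SIG%04d", seq_len(g))
  gene_ids[-seq_along(spec$signature_genes)] <-
    sprintf("BG%04d", seq_len(g - length(spec$signature_genes)))
  mu <- rnorm(g, 6, 1.5)
  col_shift <- offsets[match(meta$study, studies)] + rnorm(n, 0, spec$sigma_pair)
  x <- matrix(rnorm(g * n, 0, spec$sigma), g, n) + mu
  x <- sweep(x, 2, col_shift, "+")
  sig_idx <- seq_along(spec$signature_genes)
  case_idx <- which(meta$condition == "case")
  x[sig_idx, case_idx] <- x[sig_idx, case_idx] + spec$beta
  dimnames(x) <- list(gene_ids, meta$sample_id)
  list(
    expression = expr_matrix(x, scale = "log2"),
    samples = meta,
    truth = list(
      delta = spec$target_delta,
      beta = spec$beta,
      signature_genes = spec$signature_genes,
      study_offsets = unname(offsets),
      sigma = spec$sigma,
      sigma_pair = spec$sigma_pair
    )
  )
}

#' Generate a matched-pair replicate (cell-line style) design
#'
#' Emulates the lymphoblastoid cell-line experiment: `n_pairs` case/control
#' line pairs (sex-matched within pair), each line profiled in
#' `n_replicates`, with a within-pair correlated baseline, planted
#' up-regulated and down-regulated genes in case lines, and a designated
#' factor gene (default `"DUX4"`) given positive normalized counts in every
#' case sample. Optionally a chosen number of control samples of the last
#' pair "leak" low positive factor counts, mimicking a control line with
#' detectable transcripts in a subset of replicates.
#'
#' The expression matrix is emitted on the linear scale (strictly positive
#' values, `2^log2-signal`, plus the factor-count row), so the full pipeline
#' path — detection calls on counts, [log_transform()], [rank_genes()] — can
#' be exercised end to end.
#'
#' @param n_pairs Number of case/control line pairs.
#' @param n_replicates Replicates per line.
#' @param n_genes Background gene universe size (excluding the factor gene).
#' @param n_up,n_down Numbers of planted up-/down-regulated genes in cases.
#' @param effect_size Planted |log2 fold change|.
#' @param sigma Residual sd, log2 units.
#' @param sigma_pair Sd of the shared within-pair baseline.
#' @param factor_gene Name of the factor transcript row.
#' @param factor_mean Mean normalized count of the factor in case samples.
#' @param leak_controls Number of control samples (taken from the last pair)
#'   that receive low positive factor counts.
#' @param leak_mean Mean normalized factor count in leaking controls.
#' @param seed Integer seed.
#' @return List with `expression` (linear [expr_matrix]), `samples`, `truth`.
#' @export
generate_paired_replicates <- function(n_pairs = 3, n_replicates = 3,
                                       n_genes = 2000, n_up = 237,
                                       n_down = 263, effect_size = 2,
                                       sigma = 0.5, sigma_pair = 0.5,
                                       factor_gene = "DUX4",
                                       factor_mean = 20,
                                       leak_controls = 0, leak_mean = 0.5,
                                       seed = 1) {
  if (n_pairs < 1 || n_replicates < 1) abort("Need n_pairs >= 1 and n_replicates >= 1.")
  if (n_up + n_down > n_genes) abort("n_up + n_down must not exceed n_genes.")
  set.seed(seed)
  sexes <- rep(c("F", "M"), length.out = n_pairs)
  meta <- purrr::map(seq_len(n_pairs), function(p) {
    tibble::tibble(
      sample_id = c(
        sprintf("pair%d_case_rep%d", p, seq_len(n_replicates)),
        sprintf("pair%d_ctrl_rep%d", p, seq_len(n_replicates))
      ),
      condition = rep(c("case", "control"), each = n_replicates),
      study = "LCL",
      group = sprintf("pair%d", p),
      sex = sexes[p],
      cell_type = "LCL"
    )
  }) |> dplyr::bind_rows()
  n <- nrow(meta)
  up_genes <- sprintf("UP%04d", seq_len(n_up))
  down_genes <- sprintf("DN%04d", seq_len(n_down))
  bg_genes <- sprintf("BG%04d", seq_len(n_genes - n_up - n_down))
  gene_ids <- c(up_genes, down_genes, bg_genes)
  mu <- rnorm(n_genes, 6, 1.5)
  pair_base <- setNames(rnorm(n_pairs, 0, sigma_pair), sprintf("pair%d", seq_len(n_pairs)))
  x <- matrix(rnorm(n_genes * n, 0, sigma), n_genes, n) + mu
  x <- sweep(x, 2, pair_base[meta$group], "+")
  case_idx <- which(meta$condition == "case")
  x[seq_len(n_up), case_idx] <- x[seq_len(n_up), case_idx] + effect_size
  x[n_up + seq_len(n_down), case_idx] <- x[n_up + seq_len(n_down), case_idx] - effect_size
  linear <- 2^x
  factor_counts <- numeric(n)
  factor_counts[case_idx] <- factor_mean * runif(length(case_idx), 0.5, 1.5)
  leak_ids <- character(0)
  if (leak_controls > 0) {
    ctrl_last <- meta$sample_id[meta$condition == "control" &
      meta$group == sprintf("pair%d", n_pairs)]
    if (leak_controls > length(ctrl_last)) {
      abort("`leak_controls` exceeds the replicates of the last control line.")
    }
    leak_ids <- ctrl_last[seq_len(leak_controls)]
    factor_counts[match(leak_ids, meta$sample_id)] <-
      leak_mean * runif(leak_controls, 0.5, 1.5)
  }
  vals <- rbind(matrix(factor_counts, 1, n, dimnames = list(factor_gene, NULL)), linear)
  dimnames(vals) <- list(c(factor_gene, gene_ids), meta$sample_id)
  list(
    expression = expr_matrix(vals, scale = "linear"),
    samples = meta,
    truth = list(
      up_genes = up_genes, down_genes = down_genes,
      effect_size = effect_size, factor_gene = factor_gene,
      leak_samples = leak_ids
    )
  )
}
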