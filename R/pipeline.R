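#' Run configuration for the pipeline commands
#'
#' Each `cmd_*()` function takes a configuration: a named list, or the path of
#' a YAML file holding one. Flag-style overrides win over file values. Paths
#' are validated when the command that needs them runs. Every command writes a
#' machine-readable run manifest (`run_manifest.json`: config hash, seed,
#' input file checksums, package version) alongside its outputs, and logs
#' progress to stderr; numeric outputs never go to stderr.
#'
#' @param config A named list or YAML file path.
#' @param ... Named overrides (win over file/list values).
#' @return The merged configuration list.
#' @export
run_config <- function(config = list(), ...) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a list or a YAML file path.")
  overrides <- list(...)
  config[names(overrides)] <- overrides
  if (!is.null(config$seed)) {
    if (config$seed < 0) abort("`seed` must be a non-negative integer.")
    config$seed <- as.integer(config$seed)
  }
  config
}

write_manifest <- function(out_dir, command, config, inputs = character(0)) {
  cfg_hash <- unname(tools::md5sum(
    local({
      f <- tempfile()
      writeLines(deparse(config[order(names(config))]), f)
      f
    })
  ))
  inputs <- inputs[file.exists(inputs)]
  manifest <- list(
    command = command,
    config = config,
    config_hash = cfg_hash,
    seed = config$seed,
    inputs = as.list(tools::md5sum(inputs)),
    package_version = as.character(utils::packageVersion("sigscore"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, null = "null"
  )
}

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

log_info <- function(...) message("[sigscore] ", sprintf(...))

#' Simulate synthetic datasets
#'
#' Writes a multi-study cohort (expression TSV, sample CSV, planted-signature
#' GMT, ground-truth JSON) and, if requested, a matched-pair replicate design
#' and single-cell burst counts, all into `config$out`.
#'
#' Config keys: `out`, `seed`, optional lists `cohort`, `paired`, `burst`
#' whose entries override the corresponding generator defaults; set `paired`
#' or `burst` to `TRUE` (or a list) to enable them.
#'
#' @param config See [run_config()].
#' @param ... Overrides.
#' @return Invisibly, the list of generated objects.
#' @export
cmd_simulate <- function(config = list(), ...) {
  config <- run_config(config, ...)
  out <- ensure_dir(config$out %||% ".")
  seed <- config$seed %||% 1L
  cohort_args <- config$cohort %||% list()
  cohort_args$seed <- cohort_args$seed %||% seed
  spec <- do.call(cohort_spec, cohort_args)
  cohort <- generate_cohort(spec)
  write_expression_matrix(cohort$expression, file.path(out, "cohort_expression.tsv"))
  readr::write_csv(cohort$samples, file.path(out, "cohort_samples.csv"), progress = FALSE)
  write_gmt(
    gene_set("planted_signature", cohort$truth$signature_genes),
    file.path(out, "cohort_signature.gmt")
  )
  jsonlite::write_json(cohort$truth, file.path(out, "cohort_truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  log_info(
    "cohort: %d genes x %d samples, planted delta = %.3f",
    nrow(cohort$expression), ncol(cohort$expression), cohort$truth$delta
  )
  results <- list(cohort = cohort)
  if (!is.null(config$paired) && !isFALSE(config$paired)) {
    pr_args <- if (is.list(config$paired)) config$paired else list()
    pr_args$seed <- pr_args$seed %||% (seed + 1L)
    paired <- do.call(generate_paired_replicates, pr_args)
    write_expression_matrix(paired$expression, file.path(out, "paired_expression.tsv"))
    readr::write_csv(paired$samples, file.path(out, "paired_samples.csv"), progress = FALSE)
    results$paired <- paired
    log_info("paired design: %d samples", ncol(paired$expression))
  }
  if (!is.null(config$burst) && !isFALSE(config$burst)) {
    b_args <- if (is.list(config$burst)) config$burst else list()
    b_args$seed <- b_args$seed %||% (seed + 2L)
    bspec <- do.call(burst_spec, b_args)
    burst <- generate_burst_cells(bspec)
    write_expression_matrix(burst$expression, file.path(out, "burst_expression.tsv"))
    readr::write_csv(burst$cells, file.path(out, "burst_cells.csv"), progress = FALSE)
    results$burst <- burst
    log_info("burst model: %d cells", ncol(burst$expression))
  }
  write_manifest(out, "simulate", config)
  invisible(results)
}

#' Score signatures on an expression matrix
#'
#' Config keys: `expr` (TSV path), `sets` (GMT path), `meta` (sample table
#' path), `scale` (`"linear"`/`"log2"`, default linear), `normalize` (logical,
#' apply within-study log + quantile normalization; default FALSE), `pseudocount`,
#' `grouping` (`"group"`/`"study"`/`"none"`), `out`.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the score tibble (also written to `scores.tsv`).
#' @export
cmd_score <- function(config = list(), ...) {
  config <- run_config(config, ...)
  for (key in c("expr", "sets", "meta")) {
    if (is.null(config[[key]])) abort(paste0("Config key '", key, "' is required."))
    if (!file.exists(config[[key]])) {
      abort(paste0("Config key '", key, "': file not found: ", config[[key]]))
    }
  }
  out <- ensure_dir(config$out %||% ".")
  m <- read_expression_matrix(config$expr, scale = config$scale %||% "linear")
  sets <- pair_signed_sets(read_gmt(config$sets))
  meta <- read_sample_table(config$meta)
  if (isTRUE(config$normalize)) {
    m <- normalize_within_study(m, meta,
      quantile = !isFALSE(config$quantile),
      pseudocount = config$pseudocount %||% 1
    )
    log_info("normalized within study (log + quantile)")
  }
  scores <- withCallingHandlers(
    score_panel(m, sets, meta, grouping = config$grouping %||% "group"),
    warning = function(w) {
      log_info("scoring: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  write_scores(scores, file.path(out, "scores.tsv"))
  write_manifest(out, "score", config,
    inputs = c(config$expr, config$sets, config$meta)
  )
  log_info("scored %d signatures on %d samples", length(sets), ncol(m))
  invisible(scores)
}

#' Evaluate scored signatures as biomarkers
#'
#' Pooled ROC/AUC and Wilcoxon per signature (on z-normalized scores), plus a
#' per-study Wilcoxon table; studies with one class absent are reported as
#' skipped and the run continues. Writes `evaluation.json`, `roc_points.tsv`
#' and `study_tests.tsv`.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the evaluation tibble.
#' @export
cmd_evaluate <- function(config = list(), ...) {
  config <- run_config(config, ...)
  if (is.null(config$scores)) abort("Config key 'scores' is required.")
  if (!file.exists(config$scores)) {
    abort(paste0("Scores file not found: ", config$scores))
  }
  out <- ensure_dir(config$out %||% ".")
  scores <- read_scores(config$scores)
  ev <- evaluate_scores(scores)
  jsonlite::write_json(
    purrr::map(split(ev, ev$signature), function(r) {
      list(auc = r$auc, U = r$U, p = r$p, n_case = r$n_case, n_control = r$n_control)
    }),
    file.path(out, "evaluation.json"),
    auto_unbox = TRUE, digits = NA
  )
  curves <- purrr::map2(ev$roc, ev$signature, function(r, s) {
    dplyr::mutate(r$curve, signature = s)
  }) |> dplyr::bind_rows()
  readr::write_tsv(curves, file.path(out, "roc_points.tsv"), progress = FALSE)
  per_study <- scores |>
    dplyr::group_by(.data$signature, .data$study) |>
    dplyr::group_map(function(d, key) {
      x <- d$z_score[d$condition == "case"]
      y <- d$z_score[d$condition == "control"]
      if (length(x) == 0 || length(y) == 0) {
        log_info(
          "study '%s' skipped for '%s': one class absent",
          key$study, key$signature
        )
        return(NULL)
      }
      w <- wilcoxon_rank_sum(x, y)
      tibble::tibble(
        signature = key$signature, study = key$study,
        U = w$U, p = w$p, n_case = length(x), n_control = length(y)
      )
    }) |>
    dplyr::bind_rows()
  readr::write_tsv(per_study, file.path(out, "study_tests.tsv"), progress = FALSE)
  write_manifest(out, "evaluate", config, inputs = config$scores)
  invisible(ev)
}

#' Meta-analysis of one signature across studies
#'
#' Config keys: `scores`, `signature` (required when several are present),
#' `out`. Writes `meta.json` (per-study effects, pooled random-effects
#' estimate, tau2, Fisher combined p) and `forest.tsv`. One-class studies are
#' skipped with a message.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, the `meta_result`.
#' @export
cmd_meta <- function(config = list(), ...) {
  config <- run_config(config, ...)
  if (is.null(config$scores)) abort("Config key 'scores' is required.")
  if (!file.exists(config$scores)) {
    abort(paste0("Scores file not found: ", config$scores))
  }
  out <- ensure_dir(config$out %||% ".")
  scores <- read_scores(config$scores)
  if (!is.null(config$signature)) {
    scores <- dplyr::filter(scores, .data$signature == !!config$signature)
    if (nrow(scores) == 0) {
      abort(paste0("No scores for signature '", config$signature, "'."))
    }
  }
  keep <- scores |>
    dplyr::group_by(.data$study) |>
    dplyr::filter(dplyr::n_distinct(.data$condition) == 2) |>
    dplyr::ungroup()
  skipped <- setdiff(unique(scores$study), unique(keep$study))
  for (st in skipped) log_info("study '%s' skipped: one class absent", st)
  effects <- study_effects(keep)
  meta <- pool_random_effects(effects)
  jsonlite::write_json(
    c(
      list(studies = effects),
      glance.meta_result(meta)
    ),
    file.path(out, "meta.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  readr::write_tsv(forest_table(meta), file.path(out, "forest.tsv"), progress = FALSE)
  write_manifest(out, "meta", config, inputs = config$scores)
  log_info(
    "pooled = %.3f [%.3f, %.3f], Fisher p = %.3g",
    meta$pooled, meta$ci_lo, meta$ci_hi, meta$fisher_p
  )
  invisible(meta)
}

#' Correlation and covariate-association analyses
#'
#' Config keys: `scores`, `meta` (sample table path; needed for covariate
#' regression), `covariates` (optional names), `out`. Writes
#' `correlations.tsv` and, when covariates are available, `regression.tsv`.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, list of the two tibbles.
#' @export
cmd_associate <- function(config = list(), ...) {
  config <- run_config(config, ...)
  if (is.null(config$scores)) abort("Config key 'scores' is required.")
  if (!file.exists(config$scores)) {
    abort(paste0("Scores file not found: ", config$scores))
  }
  out <- ensure_dir(config$out %||% ".")
  scores <- read_scores(config$scores)
  cors <- correlation_matrix(scores)
  readr::write_tsv(cors, file.path(out, "correlations.tsv"), progress = FALSE)
  reg <- NULL
  if (!is.null(config$meta)) {
    meta <- read_sample_table(config$meta)
    covs <- config$covariates %||% covariate_names(meta)
    if (length(covs) > 0) {
      reg <- associate_covariates(scores, meta, covariates = unlist(covs))
      readr::write_tsv(reg, file.path(out, "regression.tsv"), progress = FALSE)
    } else {
      log_info("no covariate columns found; regression skipped")
    }
  }
  write_manifest(out, "associate", config,
    inputs = c(config$scores, config$meta %||% character(0))
  )
  invisible(list(correlations = cors, regression = reg))
}

#' Derive an up-regulated signature from an expression experiment
#'
#' Config keys: `expr`, `meta`, `scale`, `pseudocount`, `top_k` (default 500),
#' `name`, `out`. Linear-scale input is log-transformed first. Writes
#' `ranking.tsv` and `derived_signature.gmt`.
#'
#' @inheritParams cmd_simulate
#' @return Invisibly, list of the ranking and the derived [gene_set].
#' @export
cmd_derive <- function(config = list(), ...) {
  config <- run_config(config, ...)
  for (key in c("expr", "meta")) {
    if (is.null(config[[key]])) abort(paste0("Config key '", key, "' is required."))
    if (!file.exists(config[[key]])) {
      abort(paste0("Config key '", key, "': file not found: ", config[[key]]))
    }
  }
  out <- ensure_dir(config$out %||% ".")
  m <- read_expression_matrix(config$expr, scale = config$scale %||% "linear")
  if (expr_scale(m) == "linear") {
    m <- log_transform(m, pseudocount = config$pseudocount %||% 1)
  }
  meta <- read_sample_table(config$meta)
  ranking <- rank_genes(m, meta)
  sig <- derive_up_signature(ranking,
    top_k = config$top_k %||% 500,
    name = config$name %||% "derived_up"
  )
  write_ranking(ranking, file.path(out, "ranking.tsv"))
  write_gmt(sig, file.path(out, "derived_signature.gmt"))
  write_manifest(out, "derive", config, inputs = c(config$expr, config$meta))
  counts <- attr(sig, "counts")
  log_info("derived %d up-regulated genes among top %d", counts[1], counts[2])
  invisible(list(ranking = ranking, signature = sig))
}
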