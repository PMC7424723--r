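#' Read or validate a per-sample metadata table
#'
#' The sample table carries the labels the pipeline conditions on: `condition`
#' (`case`/`control`), `study`, `group` (the matched pair or control group used
#' for z-normalization), and optionally `sex`, `cell_type` and named numeric
#' disease-activity covariates (e.g. pathology score, inflammation, active
#' disease, STIR, T1, fat fraction).
#'
#' `read_sample_table()` accepts comma- or tab-separated text (sniffed from the
#' header line); `as_sample_table()` validates an existing data frame.
#' Covariate columns are parsed as numeric where possible; blank cells become
#' missing values and are preserved (downstream regression uses listwise
#' deletion).
#'
#' @param path File path.
#' @return A tibble with at least `sample_id`, `condition`, `study`, `group`.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  df <- readr::read_delim(path,
    delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  as_sample_table(df)
}

#' @rdname read_sample_table
#' @param df A data frame of per-sample metadata.
#' @export
as_sample_table <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("sample_id", "condition", "study", "group")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Sample table lacks required column(s): ", toString(missing_cols)))
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate sample_id: ", toString(head(dup, 5))))
  }
  bad_cond <- setdiff(unique(df$condition), c("case", "control"))
  if (length(bad_cond) > 0) {
    abort(paste0(
      "condition must be 'case' or 'control'; found: ", toString(bad_cond)
    ))
  }
  if ("sex" %in% names(df)) {
    df$sex[is.na(df$sex) | df$sex == ""] <- "unknown"
    bad_sex <- setdiff(unique(df$sex), c("F", "M", "unknown"))
    if (length(bad_sex) > 0) {
      abort(paste0("sex must be F, M or unknown; found: ", toString(bad_sex)))
    }
  }
  known <- c("sample_id", "condition", "study", "group", "sex", "cell_type")
  for (cl in setdiff(names(df), known)) {
    if (is.character(df[[cl]])) {
      vals <- df[[cl]]
      vals[vals == ""] <- NA_character_
      num <- suppressWarnings(as.numeric(vals))
      # keep as text only if some non-blank cell is genuinely non-numeric
      if (!any(!is.na(vals) & is.na(num))) df[[cl]] <- num
    }
  }
  df
}

#' Covariate column names in a sample table
#'
#' @param meta A sample table.
#' @return Character vector of covariate column names (everything beyond the
#'   reserved label columns).
#' @export
covariate_names <- function(meta) {
  setdiff(
    names(meta),
    c("sample_id", "condition", "study", "group", "sex", "cell_type")
  )
}
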