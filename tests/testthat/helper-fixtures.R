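# Shared fixture builders: everything is generated in code at test time.

make_expr <- function(values, genes = NULL, samples = NULL, scale = "linear") {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  expr_matrix(values, scale = scale)
}

random_expr <- function(n_genes, n_samples, seed = 1, scale = "log2",
                        mean = 6, sd = 1) {
  set.seed(seed)
  make_expr(
    matrix(rnorm(n_genes * n_samples, mean, sd), n_genes, n_samples),
    scale = scale
  )
}

simple_meta <- function(sample_ids, condition, study = "s1", group = NULL,
                        sex = "unknown") {
  tibble::tibble(
    sample_id = sample_ids,
    condition = condition,
    study = study,
    group = group %||% study,
    sex = sex,
    cell_type = "cell"
  )
}

`%||%` <- rlang::`%||%`
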