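# One full scoring -> z-normalization -> per-study effects -> pooling pass
# over a generated seven-study cohort. The gene universe is kept small; the
# score-level behaviour (which is what these checks measure) depends on the
# signature size, noise and pair variance, not on how many background genes
# ride along.
run_meta_rep <- function(seed, beta = NULL, target_delta = NULL,
                         n_genes = 40, signature_size = 20) {
  sp <- cohort_spec(
    n_genes = n_genes, signature_size = signature_size,
    beta = beta, target_delta = target_delta, seed = seed
  )
  co <- generate_cohort(sp)
  s <- mean_signature_score(co$expression, gene_set("sig", co$truth$signature_genes))
  z <- z_normalize(s, setNames(co$samples$study, co$samples$sample_id))
  effects <- dplyr::bind_rows(lapply(
    split(seq_along(z), co$samples$study),
    function(idx) {
      study_effect(unname(z[idx]), co$samples$condition[idx],
        co$samples$study[idx][1]
      )
    }
  ))
  pool_random_effects(effects)
}
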