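test_that("cohort generation is deterministic and shaped by its spec", {
  spec <- cohort_spec(n_genes = 100, signature_size = 20, seed = 9)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(unclass(a$expression)[, ], unclass(b$expression)[, ])
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)

  c2 <- generate_cohort(cohort_spec(n_genes = 100, signature_size = 20, seed = 10))
  expect_false(identical(unclass(a$expression)[, ], unclass(c2$expression)[, ]))
  expect_identical(dim(a$expression), dim(c2$expression))
  expect_identical(names(a$truth), names(c2$truth))

  expect_equal(ncol(a$expression), sum(spec$n_case) + sum(spec$n_control))
  expect_equal(nrow(a$expression), 100)
  expect_equal(sum(a$samples$condition == "case"), sum(spec$n_case))
  expect_equal(dplyr::n_distinct(a$samples$study), 7)
  # every sample in exactly one study and group
  expect_equal(anyDuplicated(a$samples$sample_id), 0)
})

test_that("cohort spec validates its fields and solves beta from delta", {
  expect_error(cohort_spec(n_case = c(5, 5), n_control = 5), "per study")
  expect_error(cohort_spec(n_case = c(1, 5), n_control = c(5, 5)), "at least 2")
  expect_error(cohort_spec(sigma = -1), "non-negative")
  expect_error(cohort_spec(signature_size = 0), "signature_size")

  sp <- cohort_spec(target_delta = 0.43, sigma = 1, sigma_pair = 0.5, signature_size = 237)
  expect_equal(sp$beta, 0.43 * sqrt(0.25 + 1 / 237), tolerance = 1e-12)
  sp2 <- cohort_spec(beta = 0.2)
  expect_equal(sp2$target_delta, 0.2 / sqrt(0.25 + 1 / 237), tolerance = 1e-12)
})

test_that("null cohorts give chance-level AUC and planted ones a shifted score", {
  null_spec <- cohort_spec(
    n_case = c(125, 125), n_control = c(125, 125),
    n_genes = 100, signature_size = 20, beta = 0, seed = 11
  )
  co <- generate_cohort(null_spec)
  s <- mean_signature_score(co$expression, gene_set("sig", co$truth$signature_genes))
  z <- z_normalize(s, setNames(co$samples$study, co$samples$sample_id))
  a <- roc_auc(unname(z), co$samples$condition)$auc
  expect_lt(abs(a - 0.5), 0.05)

  planted <- generate_cohort(cohort_spec(
    n_case = c(200, 200), n_control = c(200, 200),
    n_genes = 100, signature_size = 20, target_delta = 1, seed = 12
  ))
  s2 <- mean_signature_score(planted$expression, gene_set("sig", planted$truth$signature_genes))
  d <- mean(s2[planted$samples$condition == "case"]) -
    mean(s2[planted$samples$condition == "control"])
  expect_equal(d, planted$truth$beta, tolerance = 0.15)
})

test_that("per-gene marginal variance matches the variance decomposition", {
  spec <- cohort_spec(
    n_case = rep(100, 10), n_control = rep(100, 10),
    n_genes = 300, signature_size = 10, beta = 0,
    sigma = 1, sigma_pair = 0.5, seed = 13
  )
  co <- generate_cohort(spec)
  x <- unclass(co$expression)
  gene_vars <- apply(x, 1, var)
  offs <- co$truth$study_offsets
  w <- table(co$samples$study)[sprintf("study%d", 1:10)] / ncol(x)
  off_var <- sum(w * (offs - sum(w * offs))^2)
  expected <- spec$sigma^2 + spec$sigma_pair^2 + off_var
  expect_lt(abs(mean(gene_vars) - expected) / expected, 0.1)
})

test_that("paired replicate designs mirror the cell-line layout", {
  pr <- generate_paired_replicates(n_pairs = 3, n_replicates = 3, n_genes = 200,
    n_up = 20, n_down = 20, seed = 14
  )
  expect_equal(ncol(pr$expression), 18)
  expect_equal(sum(pr$samples$condition == "case"), 9)
  expect_equal(dplyr::n_distinct(pr$samples$group), 3)
  expect_equal(expr_scale(pr$expression), "linear")
  # sex constant within pair
  sex_by_pair <- pr$samples |>
    dplyr::distinct(group, sex)
  expect_equal(nrow(sex_by_pair), 3)

  # factor positive in all case samples, absent in all controls
  calls <- dux4_positive(pr$expression)
  meta <- pr$samples
  expect_true(all(calls$positive[match(
    meta$sample_id[meta$condition == "case"], calls$sample_id
  )]))
  expect_false(any(calls$positive[match(
    meta$sample_id[meta$condition == "control"], calls$sample_id
  )]))
})

test_that("control leak produces exactly the requested positive controls", {
  pr <- generate_paired_replicates(n_pairs = 3, n_replicates = 3, n_genes = 50,
    n_up = 5, n_down = 5, leak_controls = 2, seed = 15
  )
  calls <- dux4_positive(pr$expression)
  ctrl <- pr$samples$sample_id[pr$samples$condition == "control"]
  pos_ctrl <- calls$sample_id[calls$positive & calls$sample_id %in% ctrl]
  expect_length(pos_ctrl, 2)
  expect_setequal(pos_ctrl, pr$truth$leak_samples)
  # 2/9 controls, 9/9 cases
  expect_equal(sum(calls$positive), 9 + 2)

  zero <- generate_paired_replicates(n_pairs = 2, n_replicates = 2, n_genes = 20,
    n_up = 3, n_down = 3, factor_mean = 0, seed = 16
  )
  expect_equal(sum(dux4_positive(zero$expression)$positive), 0)
})

test_that("planted up/down effects are recoverable through the derivation path", {
  pr <- generate_paired_replicates(n_pairs = 3, n_replicates = 3, n_genes = 400,
    n_up = 30, n_down = 30, effect_size = 2, seed = 17
  )
  m <- log_transform(pr$expression)
  r <- rank_genes(m, pr$samples)
  s <- derive_up_signature(r, top_k = 60)
  expect_gt(mean(pr$truth$up_genes %in% s$genes), 0.9)
  expect_equal(sum(pr$truth$down_genes %in% s$genes), 0)
})

test_that("burst cells are deterministic, spec-validated and background-limited", {
  spec <- burst_spec(n_cells = 500, seed = 18)
  a <- generate_burst_cells(spec)
  b <- generate_burst_cells(spec)
  expect_identical(unclass(a$expression)[, ], unclass(b$expression)[, ])
  expect_identical(a$cells, b$cells)
  expect_equal(ncol(a$expression), 500)
  expect_equal(
    nrow(a$expression),
    1 + spec$n_early + spec$n_late + spec$n_background
  )

  expect_error(burst_spec(p_burst = 1.5), "0, 1")
  expect_error(burst_spec(tau_decay = -1), "non-negative")

  # with no bursts, detections are limited to the background rate
  quiet <- generate_burst_cells(burst_spec(
    n_cells = 2000, p_burst = 0,
    lambda_bg = 1e-4, seed = 19
  ))
  frac <- mean(unclass(quiet$expression)["DUX4", ] > 0)
  expect_lte(frac, 3 * (1 - exp(-1e-4)) + 3 / 2000)
})

test_that("factor-positive fraction sits near the single-cell detection rate", {
  b <- generate_burst_cells(burst_spec(seed = 20)) # 5133 cells
  frac <- mean(unclass(b$expression)["DUX4", ] > 0)
  # expected 0.5%; allow ~3 binomial sd
  expect_lt(abs(frac - 0.005), 3 * sqrt(0.005 * 0.995 / 5133))
})

test_that("factor decays while targets rise: the burst dissociation pattern", {
  b <- generate_burst_cells(burst_spec(n_cells = 5000, seed = 21))
  x <- unclass(b$expression)
  early <- colMeans(x[b$gene_sets$early, ])
  late <- colMeans(x[b$gene_sets$late, ])
  expect_lte(cor(x["DUX4", ], late), 0.25)
  expect_gte(cor(early, late), 0.3)
  # mechanism: among burst cells, the factor count falls with age and the
  # late-target score rises with age
  burst_cells <- b$cells$burst
  expect_lt(cor(b$cells$age[burst_cells], x["DUX4", burst_cells]), 0)
  expect_gt(cor(b$cells$age[burst_cells], late[burst_cells]), 0)
})
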