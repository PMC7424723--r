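# Enumeration oracle: exact two-sided rank-sum p by brute force over all
# case/control labelings of the pooled values (tie-free data only).
enumerate_exact_p <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  n <- length(pooled)
  u_obs <- sum(rank(pooled)[seq_len(nx)]) - nx * (nx + 1) / 2
  labelings <- combn(n, nx, simplify = FALSE)
  u_all <- vapply(labelings, function(idx) {
    sum(rank(pooled)[idx]) - nx * (nx + 1) / 2
  }, numeric(1))
  mu <- nx * (n - nx) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

test_that("exact Wilcoxon p matches full enumeration of labelings", {
  x <- c(1, 2)
  y <- c(3, 4)
  w <- wilcoxon_rank_sum(x, y, mode = "auto")
  expect_equal(w$method, "exact")
  expect_equal(w$U, 0)
  expect_equal(w$p, 1 / 3, tolerance = 1e-12)
  expect_equal(enumerate_exact_p(x, y), 1 / 3, tolerance = 1e-12)

  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(4)
    y <- rnorm(5)
    w <- wilcoxon_rank_sum(x, y, mode = "exact")
    expect_equal(w$p, enumerate_exact_p(x, y), tolerance = 1e-12)
    # and agrees with the reference implementation
    expect_equal(w$p, wilcox.test(x, y, exact = TRUE)$p.value, tolerance = 1e-12)
  }
})

test_that("complete ties give U = n/2 scaled and p = 1", {
  w <- wilcoxon_rank_sum(5, 5)
  expect_equal(w$U, 0.5)
  expect_equal(w$p, 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
  expect_error(wilcoxon_rank_sum(c(1, 1), c(1, 2), mode = "exact"), "tie")
})

test_that("strongly separated large samples give a vanishing p", {
  set.seed(11)
  x <- rnorm(50, 2, 1)
  y <- rnorm(50, 0, 1)
  w <- wilcoxon_rank_sum(x, y)
  expect_equal(w$method, "approx")
  expect_lt(w$p, 1e-6)
})

test_that("normal approximation tracks the exact p over all 6v6 splits", {
  # exhaustive: all C(12,6) = 924 case/control splits of a fixed tie-free set
  vals <- c(0.31, 0.77, 1.21, 1.64, 2.05, 2.57, 3.1, 3.62, 4.4, 5.03, 5.9, 7.2)
  splits <- combn(12, 6, simplify = FALSE)
  dmax <- 0
  for (idx in splits) {
    x <- vals[idx]
    y <- vals[-idx]
    pe <- wilcoxon_rank_sum(x, y, mode = "exact")$p
    pa <- wilcoxon_rank_sum(x, y, mode = "approx")$p
    dmax <- max(dmax, abs(pe - pa))
  }
  expect_lte(dmax, 0.02)
})

test_that("AUC honors the U equivalence and the stated toy examples", {
  r1 <- roc_auc(c(3, 4, 1, 2), c("case", "case", "control", "control"))
  expect_equal(r1$auc, 1)
  r2 <- roc_auc(c(1, 3, 2, 4), c("case", "case", "control", "control"))
  expect_equal(r2$auc, 0.25) # brute force: 1 concordant of 4 pairs
  r3 <- roc_auc(rep(2, 6), rep(c("case", "control"), 3))
  expect_equal(r3$auc, 0.5)

  # U equivalence on random tied data
  set.seed(13)
  sc <- sample(1:5, 40, replace = TRUE)
  lab <- rep(c("case", "control"), 20)
  r <- roc_auc(sc, lab)
  expect_equal(r$auc, r$U / (r$n_case * r$n_control), tolerance = 1e-12)

  expect_error(roc_auc(1:4, rep("case", 4)), "Both classes")
})

test_that("ROC curve is monotone from (0,0) to (1,1)", {
  set.seed(17)
  sc <- c(rnorm(15, 1), rnorm(12))
  lab <- rep(c("case", "control"), c(15, 12))
  r <- roc_auc(sc, lab)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
})

test_that("AUC respects complement and monotone-transform invariances", {
  set.seed(19)
  sc <- c(rnorm(10, 0.5), rnorm(10))
  sc[3] <- sc[12] # force a tie
  lab <- rep(c("case", "control"), each = 10)
  a <- roc_auc(sc, lab)$auc
  expect_equal(a + roc_auc(-sc, lab)$auc, 1, tolerance = 1e-12)
  expect_equal(roc_auc(exp(sc), lab)$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(3 * sc + 10, lab)$auc, a, tolerance = 1e-12)
})

test_that("AUC and Wilcoxon agree with pROC on shared data", {
  skip_if_not_installed("pROC")
  set.seed(23)
  sc <- c(rnorm(20, 0.8), rnorm(25))
  lab <- rep(c("case", "control"), c(20, 25))
  r <- roc_auc(sc, lab)
  ref <- pROC::roc(
    response = factor(lab, levels = c("control", "case")),
    predictor = sc, quiet = TRUE, direction = "<"
  )
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("empirical AUC matches the closed-form normal link", {
  # for N(delta,1) vs N(0,1) scores, AUC = pnorm(delta / sqrt(2))
  set.seed(29)
  delta <- 1
  x <- rnorm(5000, delta)
  y <- rnorm(5000)
  a <- roc_auc(c(x, y), rep(c("case", "control"), each = 5000))$auc
  expect_lt(abs(a - pnorm(delta / sqrt(2))), 0.02)
})

test_that("DeLong test handles self-comparison and antisymmetry", {
  set.seed(31)
  sc <- c(rnorm(12, 2), rnorm(12))
  lab <- rep(c("case", "control"), each = 12)
  self <- delong_test(sc, sc, lab)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)

  sep <- c(3, 4, 5, 0, 1, 2)
  lab2 <- rep(c("case", "control"), each = 3)
  dl <- delong_test(sep, -sep, lab2)
  expect_equal(dl$auc_a, 1)
  expect_equal(dl$auc_b, 0)
  expect_true(is.infinite(dl$z) || abs(dl$z) > 10)

  expect_error(delong_test(sc, sc[-1], lab), "same samples")
})

test_that("DeLong variance is close to a bootstrap oracle", {
  set.seed(33)
  n <- 20
  sc_a <- c(rnorm(n, 1), rnorm(n))
  sc_b <- 0.5 * sc_a + rnorm(2 * n, 0, 0.8)
  lab <- rep(c("case", "control"), each = n)
  dl <- delong_test(sc_a, sc_b, lab)
  boots <- replicate(10000, {
    i <- sample(which(lab == "case"), n, replace = TRUE)
    j <- sample(which(lab == "control"), n, replace = TRUE)
    idx <- c(i, j)
    auc_of <- function(s) {
      x <- s[seq_len(n)]
      y <- s[-seq_len(n)]
      (sum(rank(c(x, y))[seq_len(n)]) - n * (n + 1) / 2) / (n * n)
    }
    auc_of(sc_a[idx]) - auc_of(sc_b[idx])
  })
  expect_lt(abs(dl$var_diff - var(boots)) / var(boots), 0.15)
})

test_that("DeLong agrees with pROC's paired test", {
  skip_if_not_installed("pROC")
  set.seed(37)
  n <- 30
  sc_a <- c(rnorm(n, 1), rnorm(n))
  sc_b <- 0.6 * sc_a + rnorm(2 * n)
  lab <- factor(rep(c("control", "case"), each = n), levels = c("control", "case"))
  dl <- delong_test(sc_a, sc_b, as.character(lab))
  ra <- pROC::roc(lab, sc_a, quiet = TRUE, direction = "<")
  rb <- pROC::roc(lab, sc_b, quiet = TRUE, direction = "<")
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(dl$p, ref$p.value, tolerance = 1e-9)
})

test_that("evaluate_scores reports one row per signature with pooled ROC", {
  set.seed(41)
  sf <- tibble::tibble(
    sample_id = rep(sprintf("s%d", 1:30), 2),
    signature = rep(c("sigA", "sigB"), each = 30),
    raw_score = rnorm(60),
    z_score = c(rnorm(30, rep(c(1, 0), each = 15)), rnorm(30)),
    group = "g",
    study = "st",
    condition = rep(rep(c("case", "control"), each = 15), 2)
  )
  ev <- evaluate_scores(sf)
  expect_equal(nrow(ev), 2)
  expect_gt(ev$auc[ev$signature == "sigA"], 0.5)
  expect_equal(
    ev$auc[1],
    roc_auc(sf$z_score[1:30], sf$condition[1:30])$auc
  )
})
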