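test_that("expression matrix TSV round-trips and rejects malformed input", {
  m <- make_expr(matrix(c(1.25, 2.5, 3, 4, 0, 6.125), 3, 2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m, path)
  back <- read_expression_matrix(path, scale = "linear")
  expect_identical(dim(back), c(3L, 2L))
  expect_identical(unclass(back)[, ], unclass(m)[, ])
  expect_equal(expr_scale(back), "linear")

  # values written at 10 significant digits survive a second round-trip bit-identically
  set.seed(42)
  m2 <- make_expr(matrix(signif(abs(rnorm(20, 5, 2)), 10), 5, 4))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m2, p2)
  expect_identical(unclass(read_expression_matrix(p2))[, ], unclass(m2)[, ])

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "DUX4\t1\t2", "DUX4\t3\t4"), dup)
  expect_error(read_expression_matrix(dup), "DUX4")

  na_file <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1\tNA", "g2\t3\t4"), na_file)
  err <- expect_error(read_expression_matrix(na_file))
  expect_match(conditionMessage(err), "g1")
  expect_match(conditionMessage(err), "s2")
})

test_that("expr_matrix enforces its invariants", {
  vals <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_s3_class(expr_matrix(vals, "linear"), "expr_matrix")
  neg <- vals
  neg[1, 1] <- -1
  expect_error(expr_matrix(neg, "linear"), "Negative")
  expect_s3_class(expr_matrix(neg, "log2"), "expr_matrix")
  inf <- vals
  inf[2, 2] <- Inf
  expect_error(expr_matrix(inf, "linear"), "finite")
  expect_error(expr_matrix(unname(vals), "linear"), "rownames")
})

test_that("GMT reader parses, deduplicates and rejects per spec'd format rules", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tG1\tG2", "SETB\tdesc\tG3\tG4\tG5"), path)
  sets <- read_gmt(path)
  expect_named(sets, c("SETA", "SETB"))
  expect_equal(sets$SETA$genes, c("G1", "G2"))
  expect_equal(length(sets$SETB$genes), 3)

  dup_gene <- withr::local_tempfile(fileext = ".gmt")
  writeLines("SETA\tdesc\tG1\tG1", dup_gene)
  expect_warning(sets2 <- read_gmt(dup_gene), "duplicate")
  expect_equal(sets2$SETA$genes, "G1")

  dup_name <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SETA\tdesc\tG1", "SETA\tdesc\tG2"), dup_name)
  expect_error(read_gmt(dup_name), "SETA")

  short <- withr::local_tempfile(fileext = ".gmt")
  writeLines("SETA\tdesc", short)
  expect_error(read_gmt(short), "field")
})

test_that("signed sets round-trip through paired _UP/_DOWN GMT lines", {
  s <- signed_gene_set("PAX7", c("U1", "U2", "U3"), c("D1", "D2"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(s, path)
  back <- pair_signed_sets(read_gmt(path))
  expect_s3_class(back$PAX7, "signed_gene_set")
  expect_equal(back$PAX7$up_genes, s$up_genes)
  expect_equal(back$PAX7$down_genes, s$down_genes)
  expect_error(signed_gene_set("x", c("A", "B"), c("B", "C")), "both")
})

test_that("sample table reader validates columns and parses covariates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "sample_id,condition,study,group,sex,inflammation",
    "s1,case,st1,g1,F,1.5",
    "s2,control,st1,g1,M,2",
    "s3,case,st1,g2,F,",
    "s4,control,st1,g2,M,0.5"
  ), path)
  tab <- read_sample_table(path)
  expect_equal(sort(unique(tab$condition)), c("case", "control"))
  expect_type(tab$inflammation, "double")
  expect_true(is.na(tab$inflammation[3]))
  expect_equal(covariate_names(tab), "inflammation")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,condition,study", "s1,case,st1"), bad)
  expect_error(read_sample_table(bad), "group")
})

test_that("log_transform maps linear to log2 with pseudocount and refuses log input", {
  m <- make_expr(matrix(c(0, 3, 1, 7), 2, 2))
  lt <- log_transform(m, pseudocount = 1)
  expect_equal(unclass(lt)[1, 1], 0)
  expect_equal(unclass(lt)[2, 1], 2)
  expect_equal(unclass(lt)[2, 2], 3)
  expect_equal(expr_scale(lt), "log2")
  expect_error(log_transform(lt), "log2")
  expect_error(log_transform(m, pseudocount = 0), "positive")
})

test_that("quantile normalization matches the forced 2-sample case and the tie rule", {
  m <- make_expr(cbind(c(1, 2, 3), c(4, 5, 6)))
  qn <- quantile_normalize(m)
  expect_equal(unclass(qn)[, 1], c(2.5, 3.5, 4.5), ignore_attr = TRUE)
  expect_equal(unclass(qn)[, 2], c(2.5, 3.5, 4.5), ignore_attr = TRUE)

  # identical samples are a fixed point
  ident <- make_expr(cbind(c(2, 1, 5), c(2, 1, 5)))
  expect_equal(unclass(quantile_normalize(ident))[, ], unclass(ident)[, ])

  # tie rule, hand-computed: reference = (1.5, 2, 4.5); tied 1s share mean(1.5, 2)
  tie <- make_expr(cbind(c(1, 1, 5), c(2, 3, 4)))
  qt <- quantile_normalize(tie)
  expect_equal(unclass(qt)[, 1], c(1.75, 1.75, 4.5), ignore_attr = TRUE)
  expect_equal(unclass(qt)[, 2], c(1.5, 2, 4.5), ignore_attr = TRUE)

  expect_error(quantile_normalize(make_expr(matrix(1:3, 3, 1))), "2 samples")
})

test_that("quantile normalization is idempotent and equalizes column means", {
  m <- random_expr(80, 6, seed = 7)
  q1 <- quantile_normalize(m)
  q2 <- quantile_normalize(q1)
  expect_equal(unclass(q1)[, ], unclass(q2)[, ], tolerance = 1e-12)
  cm <- colMeans(unclass(q1))
  expect_lt(max(cm) - min(cm), 1e-9)
  # within-sample rank order preserved
  expect_identical(
    apply(unclass(m), 2, order),
    apply(unclass(q1), 2, order)
  )
})

test_that("within-study normalization treats studies independently", {
  set.seed(11)
  m <- make_expr(matrix(exp(rnorm(200, 3, 1)), 20, 10))
  meta <- simple_meta(colnames(m), rep(c("case", "control"), 5),
    study = rep(c("A", "B"), each = 5)
  )
  norm <- normalize_within_study(m, meta)
  expect_equal(expr_scale(norm), "log2")
  # each study's columns share a common sorted profile; across studies they differ
  a <- unclass(norm)[, 1:5]
  b <- unclass(norm)[, 6:10]
  expect_equal(unname(sort(a[, 1])), unname(sort(a[, 3])), tolerance = 1e-12)
  expect_equal(unname(sort(b[, 1])), unname(sort(b[, 4])), tolerance = 1e-12)
  # study A's reference is computed without any influence from study B
  solo <- quantile_normalize(log_transform(m[, 1:5]))
  expect_equal(unclass(norm)[, 1:5], unclass(solo)[, ], tolerance = 1e-12)
})
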