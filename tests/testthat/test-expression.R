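mini_soft <- function(path, vals = NULL) {
  # 2 probes x 4 samples, 2 case + 2 control
  if (is.null(vals)) {
    vals <- rbind(c(200, 210, 100, 105), c(50, 55, 48, 52))
  }
  lines <- c(
    "^DATASET = mini",
    "^SUBSET = case",
    "!subset_type = disease state",
    "!subset_description = ankylosing spondylitis",
    "!subset_sample_id = S1,S2",
    "^SUBSET = control",
    "!subset_type = disease state",
    "!subset_description = control",
    "!subset_sample_id = S3,S4",
    "!dataset_table_begin",
    "ID_REF\tIDENTIFIER\tS1\tS2\tS3\tS4",
    paste(c("P1", "GENE1", vals[1, ]), collapse = "\t"),
    paste(c("P2", "GENE2", vals[2, ]), collapse = "\t"),
    "!dataset_table_end"
  )
  writeLines(lines, path)
  path
}

test_that("a minimal SOFT fixture loads with groups from disease-state subsets", {
  f <- withr::local_tempfile(fileext = ".soft")
  study <- load_expression(mini_soft(f), format = "soft")
  expect_s3_class(study, "expression_study")
  expect_equal(dim(study$matrix), c(2L, 4L))
  expect_equal(sum(study$groups == "case"), 2)
  expect_equal(sum(study$groups == "control"), 2)
  expect_equal(unname(study$probe_map["P1"]), "GENE1")
  expect_equal(study$scale, "linear")
})

test_that("TSV matrix loading errors on an unlabeled sample, naming it", {
  m <- withr::local_tempfile(lines = c("probe\tgene\tS1\tS2\tS3\tS4",
                                       "P1\tG1\t1\t2\t3\t4"))
  lab <- withr::local_tempfile(lines = c("S1\tcase", "S2\tcase", "S3\tcontrol"))
  expect_error(load_expression(m, "matrix_tsv", labels = lab), "S4")
})

test_that("log2-scale matrices are detected and exponentiated before fold change", {
  f <- withr::local_tempfile(fileext = ".soft")
  # log2 values: case = 3, control = 1 -> linear fc = 2^2 = 4
  mini_soft(f, vals = rbind(c(3, 3, 1, 1), c(-1, -1, -1, -1)))
  study <- load_expression(f, format = "soft")
  expect_equal(study$scale, "log2")
  res <- suppressWarnings(differential_expression(study, genes = "GENE1"))
  expect_equal(res$fold_change, 4)
  # explicit override wins
  study_lin <- load_expression(f, format = "soft", scale = "linear")
  expect_equal(study_lin$scale, "linear")
})

test_that("fold change is the linear-scale ratio of group means", {
  f <- withr::local_tempfile(fileext = ".soft")
  study <- load_expression(mini_soft(f, rbind(c(2, 2, 1, 1), c(5, 5, 5, 5))),
                           format = "soft")
  expect_equal(suppressWarnings(fold_change(study, "GENE1")), 2)
  expect_equal(suppressWarnings(fold_change(study, "GENE2")), 1)
})

test_that("the t-test wrapper matches a hand-computed Welch formula and handles degeneracy", {
  expect_equal(t_test_two_tailed(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_equal(t_test_two_tailed(c(4, 4), c(4, 4))$p, 1)
  expect_warning(res0 <- t_test_two_tailed(c(4, 4), c(5, 5)), "zero variance")
  expect_equal(res0$p, 0)

  set.seed(13)
  for (i in 1:25) {
    x <- stats::rnorm(sample(3:10, 1), mean = stats::runif(1, 0, 2))
    y <- stats::rnorm(sample(3:10, 1), sd = stats::runif(1, 0.5, 2))
    got <- t_test_two_tailed(x, y, "welch")
    # independent route: Welch statistic + df, then the t CDF
    se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
    tt <- (mean(x) - mean(y)) / se
    df <- se^4 / ((stats::var(x) / length(x))^2 / (length(x) - 1) +
                  (stats::var(y) / length(y))^2 / (length(y) - 1))
    expect_equal(got$t, tt, tolerance = 1e-10)
    expect_equal(got$p, 2 * stats::pt(-abs(tt), df), tolerance = 1e-10)
    # pooled route
    gotp <- t_test_two_tailed(x, y, "pooled")
    sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
      (length(x) + length(y) - 2)
    tp <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
    expect_equal(gotp$t, tp, tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the naive rank-by-rank oracle and its invariants", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(29)
  for (i in 1:30) {
    p <- stats::runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    # permutation invariance up to reordering
    perm <- sample(length(p))
    expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-12)
    # monotone: larger p never gets smaller adjusted value
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("probe-to-gene aggregation follows the configured bridge rule", {
  f <- withr::local_tempfile(fileext = ".soft")
  lines <- c(
    "^DATASET = multi",
    "^SUBSET = case", "!subset_type = disease state",
    "!subset_description = case", "!subset_sample_id = S1,S2,S3",
    "^SUBSET = control", "!subset_type = disease state",
    "!subset_description = control", "!subset_sample_id = S4,S5,S6",
    "!dataset_table_begin",
    "ID_REF\tIDENTIFIER\tS1\tS2\tS3\tS4\tS5\tS6",
    "P1\tG1\t40\t41\t42\t20\t21\t19",   # strong probe, fc ~2
    "P2\tG1\t30\t25\t35\t29\t31\t26",   # noisy probe, fc ~1
    "!dataset_table_end")
  writeLines(lines, f)
  study <- load_expression(f, format = "soft")
  min_p <- differential_expression(study, aggregate = "min_p")
  expect_equal(min_p$probe, "P1")
  mx <- differential_expression(study, aggregate = "max_abs_logfc")
  expect_equal(mx$probe, "P1")
  avg <- differential_expression(study, aggregate = "mean")
  expect_equal(avg$probe, "P1;P2")
})

test_that("nonpositive group means are rejected as unnormalized input", {
  f <- withr::local_tempfile(fileext = ".soft")
  # values include > 30 magnitudes so the scale stays linear, with a
  # negative group mean
  study <- load_expression(mini_soft(f, rbind(c(-40, -42, 10, 12),
                                              c(50, 51, 49, 50))),
                           format = "soft")
  expect_error(differential_expression(study, genes = "GENE1"), "onpositive")
})

test_that("classification labels follow nominal p and fold-change direction", {
  res <- data.frame(gene = c("A", "B", "C", "D"),
                    fold_change = c(1.436, 1.0, 0.6, 1.5),
                    p_nominal = c(0.000678, 0.001, 0.01, 0.06))
  lab <- classify_de(res, p_threshold = 0.05, fc_threshold = 1)
  expect_equal(lab$label,
               c("upregulated", "non-significant", "downregulated",
                 "non-significant"))
  expect_equal(lab$log2_fc[2], 0)
  expect_equal(lab$neg_log10_p[1], -log10(0.000678))
})

test_that("null t-test p-values are uniform and the false-positive rate is nominal", {
  set.seed(37)
  n <- 16
  pvals <- replicate(2000, {
    t_test_two_tailed(stats::rnorm(n), stats::rnorm(n))$p
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.02)
})
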