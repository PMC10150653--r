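# exact and approximate nonparametric tests, Spearman CI, methylation summaries

test_that("Mann-Whitney worked examples", {
  r <- mann_whitney_two_tailed(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_two_tailed, 0.1)   # 2 * 1/20 rank assignments
  expect_equal(r$method, "exact")

  r1 <- mann_whitney_two_tailed(5, 10)
  expect_equal(r1$statistic, 0)
  expect_equal(r1$p_two_tailed, 1.0)

  # symmetry: swapping samples leaves p unchanged
  set.seed(9)
  x <- rnorm(6); y <- rnorm(8)
  expect_equal(mann_whitney_two_tailed(x, y)$p_two_tailed,
               mann_whitney_two_tailed(y, x)$p_two_tailed)
  expect_error(mann_whitney_two_tailed(numeric(0), 1),
               class = "emtstrat_insufficient_data_error")
})

test_that("exact Mann-Whitney p equals full enumeration, with and without ties", {
  set.seed(31)
  for (n1 in 1:4) for (n2 in n1:(8 - n1)) {
    x <- round(rnorm(n1), 3); y <- round(rnorm(n2), 3)        # tie-free a.s.
    r <- mann_whitney_two_tailed(x, y)
    expect_equal(r$p_two_tailed, oracle_mw_p(x, y), tolerance = 1e-12,
                 label = sprintf("continuous n1=%d n2=%d", n1, n2))
    expect_equal(r$statistic, oracle_mw_u(x, y))

    xt <- sample(1:3, n1, TRUE); yt <- sample(1:3, n2, TRUE)  # heavy ties
    rt <- mann_whitney_two_tailed(xt, yt)
    expect_equal(rt$p_two_tailed, oracle_mw_p(xt, yt), tolerance = 1e-12,
                 label = sprintf("tied n1=%d n2=%d", n1, n2))
    expect_equal(rt$method, "exact")
  }
})

test_that("large or tied samples fall back to the corrected normal approximation", {
  set.seed(12)
  x <- rnorm(30); y <- rnorm(30, 0.5)
  r <- mann_whitney_two_tailed(x, y)
  expect_equal(r$method, "normal_approx")
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(r$p_two_tailed, unname(ref$p.value), tolerance = 1e-12)
  expect_equal(r$statistic, unname(ref$statistic))
})

test_that("Wilcoxon signed-rank worked examples", {
  x <- 1:6
  r <- wilcoxon_paired_two_tailed(x, x + 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_two_tailed, 0.03125)  # 2 * (1/2)^6, all signs negative
  expect_equal(r$method, "exact")

  r2 <- wilcoxon_paired_two_tailed(c(1, 2), c(2, 1))
  expect_equal(r2$p_two_tailed, 1.0)

  expect_error(wilcoxon_paired_two_tailed(1:3, 1:3),
               class = "emtstrat_degenerate_data_error")
  expect_error(wilcoxon_paired_two_tailed(1:3, 1:4),
               class = "emtstrat_input_error")
})

test_that("exact Wilcoxon p equals full sign enumeration up to n = 10", {
  set.seed(23)
  for (n in c(2, 4, 6, 8, 10)) {
    x <- round(rnorm(n), 3); y <- round(rnorm(n), 3)
    r <- wilcoxon_paired_two_tailed(x, y)
    expect_equal(r$p_two_tailed, oracle_wsr_p(x, y), tolerance = 1e-12,
                 label = sprintf("continuous n=%d", n))

    xt <- sample(1:4, n, TRUE); yt <- sample(1:4, n, TRUE)
    if (any(xt != yt)) {
      rt <- wilcoxon_paired_two_tailed(xt, yt)
      expect_equal(rt$p_two_tailed, oracle_wsr_p(xt, yt), tolerance = 1e-12,
                   label = sprintf("tied n=%d", n))
    }
  }
})

test_that("Spearman: hand-computed rank formula, invariances, and errors", {
  r <- spearman_with_ci(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$r, 1 - 6 * 4 / (4 * 15))  # = 0.6, no ties

  x <- 1:6
  r1 <- spearman_with_ci(x, x^2)          # monotone transform: r = 1
  expect_equal(r1$r, 1)
  expect_equal(c(r1$ci_low, r1$ci_high), c(1, 1))
  expect_gt(r1$p, 0)                       # never exactly 0

  expect_equal(spearman_with_ci(x, rev(x))$r, -1)

  # invariance under strictly monotone transforms of either variable
  set.seed(2)
  a <- runif(20); b <- runif(20)
  expect_equal(spearman_with_ci(exp(a), b)$r, spearman_with_ci(a, b)$r)
  expect_equal(spearman_with_ci(a, 3 * b + 1)$r, spearman_with_ci(a, b)$r)

  expect_error(spearman_with_ci(rep(1, 5), 1:5),
               class = "emtstrat_undefined_correlation_error")
  expect_error(spearman_with_ci(1:2, 2:1),
               class = "emtstrat_insufficient_data_error")
})

test_that("Spearman r and p agree with cor.test; CI brackets r within [-1,1]", {
  set.seed(44)
  x <- rnorm(25); y <- x + rnorm(25, 0, 2)
  ours <- spearman_with_ci(x, y)
  ref <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-3)   # same t approximation
  expect_true(ours$ci_low <= ours$r && ours$r <= ours$ci_high)
  expect_true(ours$ci_low >= -1 && ours$ci_high <= 1)
})

test_that("proportion_expressing counts strictly-above-threshold values", {
  m <- make_matrix(matrix(c(0, 0, 1, 2), ncol = 1), gene_ids = "MCAM")
  p <- proportion_expressing(m, "MCAM")
  expect_equal(p$fraction, 0.5)
  expect_equal(p$n_expressing, 2L)
  expect_equal(proportion_expressing(m, "MCAM", detection_threshold = 5)$fraction, 0)
  z <- make_matrix(matrix(0, 3, 1), gene_ids = "MCAM")
  expect_equal(proportion_expressing(z, "MCAM")$fraction, 0)
  expect_error(proportion_expressing(m, "KDR"),
               class = "emtstrat_missing_gene_error")
})

test_that("methylation mean M-values match a row loop and handle gaps", {
  tab <- methylation_table(rbind(c(1, 2, 3), c(-0.5, -0.5, -0.5)),
                           c("s1", "s2"), c("tumour", "normal"))
  s <- methylation_mean_m(tab)
  expect_equal(s$mean_M, c(2, -0.5))

  set.seed(19)
  M <- matrix(rnorm(20 * 9), 20, 9)
  M[3, 2] <- NA
  tab <- methylation_table(M, sprintf("s%02d", 1:20),
                           rep(c("tumour", "normal"), 10))
  s <- methylation_mean_m(tab)
  loop <- sapply(1:20, function(i) mean(M[i, !is.na(M[i, ])]))
  expect_equal(s$mean_M, loop)
  expect_equal(s$n_probes[3], 8)

  M[5, ] <- NA
  tab <- methylation_table(M, sprintf("s%02d", 1:20),
                           rep(c("tumour", "normal"), 10))
  expect_warning(s2 <- methylation_mean_m(tab), "no available probes")
  expect_equal(nrow(s2), 19)
})

test_that("methylation-expression correlation matches by sample id", {
  s <- data.frame(sample_id = c("a", "b", "c", "d"),
                  group = "tumour", mean_M = c(4, 3, 2, 1), n_probes = 9)
  expr <- c(a = 1, b = 2, c = 3, d = 4)
  expect_equal(methylation_expression_correlation(s, expr)$r, -1)
  expect_error(methylation_expression_correlation(s, c(zz = 1)),
               class = "emtstrat_insufficient_data_error")
  expect_error(methylation_expression_correlation(s, unname(expr)),
               class = "emtstrat_input_error")
})
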