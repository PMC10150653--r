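# EMT-class thresholds, MCAM tri-partition, nine-subpopulation summary

test_that("EMT classification follows the published boundaries", {
  thr <- threshold_config("cell")
  cls <- classify_emt(c(a = -0.01, b = 3.0, c = 7.2, d = 0, e = 5, f = 4.999))
  expect_equal(as.character(cls$emt_class),
               c("low", "med", "high", "med", "high", "med"))
  # bulk defaults: 2000 / 5000
  bulk <- classify_emt(c(s = 3000), threshold_config("bulk"))
  expect_equal(as.character(bulk$emt_class), "med")
})

test_that("threshold scale must match the matrix kind unless overridden", {
  m <- random_emt_matrix(3, seed = 2)
  tab <- score_all(m, signature_registry())
  expect_error(classify_emt(tab, threshold_config("bulk")),
               class = "emtstrat_config_error")
  expect_silent(classify_emt(tab, threshold_config("bulk"),
                             override_scale_check = TRUE))
  expect_error(threshold_config("cell", emt_low_upper = 6, emt_high_lower = 5),
               class = "emtstrat_config_error")
})

test_that("classification is monotone in the score", {
  set.seed(4)
  s <- sort(rnorm(200, 1, 4))
  cls <- classify_emt(s)$emt_class
  expect_true(all(diff(as.integer(cls)) >= 0))
})

test_that("MCAM tri-partition worked examples", {
  # no expressers
  p <- mcam_tripartition(c(0, 0, 0), rep("g", 3))
  expect_equal(as.character(p$mcam_class), rep("neg", 3))
  # odd expresser count: extra cell joins the low group
  p <- mcam_tripartition(c(0, 0.4, 1.2, 3.3), rep("g", 4))
  expect_equal(as.character(p$mcam_class), c("neg", "low", "low", "high"))
  # even split into two equal halves
  p <- mcam_tripartition(c(0.5, 1.0, 2.0, 4.0), rep("g", 4))
  expect_equal(as.character(p$mcam_class), c("low", "low", "high", "high"))
})

test_that("ties at the expresser median break by stable input order", {
  p <- mcam_tripartition(c(1, 1, 1), rep("g", 3))
  expect_equal(as.character(p$mcam_class), c("low", "low", "high"))
})

test_that("tri-partition invariants hold over random groups", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    expr <- ifelse(runif(n) < 0.4, 0, round(rexp(n, 0.5), 2))
    grp <- sample(c("a", "b"), n, replace = TRUE)
    p <- mcam_tripartition(expr, grp)
    expect_false(anyNA(p$mcam_class))
    for (g in unique(grp)) {
      i <- p$group_id == g
      nlow <- sum(p$mcam_class[i] == "low")
      nhigh <- sum(p$mcam_class[i] == "high")
      expect_true((nlow - nhigh) %in% c(0L, 1L))
      expect_true(all(expr[i][p$mcam_class[i] == "neg"] <= 0))
      expect_true(all(expr[i][p$mcam_class[i] != "neg"] > 0))
      lows <- expr[i][p$mcam_class[i] == "low"]
      highs <- expr[i][p$mcam_class[i] == "high"]
      if (length(lows) && length(highs))
        expect_lte(max(lows), min(highs))
    }
  }
})

test_that("cross_tabulate: identity on one obs per cell, oracle on 200 obs", {
  combos <- expand.grid(emt_class = c("low", "med", "high"),
                        mcam_class = c("neg", "low", "high"),
                        stringsAsFactors = FALSE)
  strata <- data.frame(obs_id = sprintf("o%d", 1:9), combos)
  scores <- data.frame(obs_id = strata$obs_id, sInv = 1:9 / 10, sCSC = (9:1) / 10)
  tab <- cross_tabulate(strata, scores)
  m <- match(paste(tab$emt_class, tab$mcam_class),
             paste(strata$emt_class, strata$mcam_class))
  expect_equal(tab$n, rep(1L, 9))
  expect_equal(tab$mean_sInv, scores$sInv[m])
  expect_equal(tab$mean_sCSC, scores$sCSC[m])

  set.seed(15)
  n <- 200
  strata <- data.frame(obs_id = sprintf("c%03d", 1:n),
                       emt_class = sample(c("low", "med", "high"), n, TRUE),
                       mcam_class = sample(c("neg", "low", "high"), n, TRUE))
  scores <- data.frame(obs_id = strata$obs_id,
                       sInv = runif(n), sCSC = runif(n))
  tab <- cross_tabulate(strata, scores)
  expect_equal(sum(tab$n), n)
  for (r in seq_len(nrow(tab))) {    # independent group-by loop
    i <- strata$emt_class == tab$emt_class[r] &
      strata$mcam_class == tab$mcam_class[r]
    expect_equal(tab$n[r], sum(i))
    if (sum(i) > 0) {
      expect_equal(tab$mean_sInv[r], mean(scores$sInv[i]))
      expect_equal(tab$mean_sCSC[r], mean(scores$sCSC[i]))
    } else {
      expect_true(is.na(tab$mean_sInv[r]))
    }
  }
})

test_that("subpopulation correlation: monotone, hand-ranked, and degenerate cases", {
  tab <- data.frame(emt_class = "x", mcam_class = "y", n = rep(5L, 9),
                    mean_sInv = 1:9, mean_sCSC = (1:9)^2)
  r <- subpopulation_correlation(tab)
  expect_equal(r$r, 1)

  # one reversed pair: hand rank-difference formula (no ties)
  tab4 <- data.frame(emt_class = "x", mcam_class = "y", n = rep(2L, 4),
                     mean_sInv = c(1, 2, 3, 4), mean_sCSC = c(2, 1, 4, 3))
  expect_equal(subpopulation_correlation(tab4)$r, 1 - 6 * 4 / (4 * 15))

  tab2 <- tab[1:2, ]
  expect_error(subpopulation_correlation(tab2),
               class = "emtstrat_insufficient_data_error")
})

test_that("expression_by_stratum groups values and runs the three pairwise tests", {
  set.seed(6)
  n <- 12
  genes <- c("CDH1", "GRHL2", "ITGB4", "KRT5", "KRT8", "FST",
             "CDH2", "ZEB1", "VIM", "MMP1", "FN1", "TGFB1I1", "OVOL2", "FLAT")
  cls <- rep(c("low", "med", "high"), each = 4)
  v <- matrix(runif(n * length(genes)), nrow = n)
  colnames(v) <- genes
  v[, "OVOL2"] <- as.integer(factor(cls, levels = c("low", "med", "high")))
  v[, "FLAT"] <- 1
  m <- make_matrix(v, gene_ids = genes)
  strata <- data.frame(obs_id = m$obs_ids, emt_class = cls)

  res <- expression_by_stratum(m, "OVOL2", strata)
  expect_equal(unname(res$n), c(4L, 4L, 4L))
  mu <- vapply(res$values, mean, numeric(1))
  expect_true(mu[["low"]] < mu[["med"]] && mu[["med"]] < mu[["high"]])

  # constant gene: exact test, all pairwise p = 1
  flat <- expression_by_stratum(m, "FLAT", strata)
  expect_equal(flat$comparisons$p_two_tailed, rep(1, 3))
  expect_equal(flat$comparisons$method, rep("exact", 3))

  expect_error(expression_by_stratum(m, "NOPE", strata),
               class = "emtstrat_missing_gene_error")
})

test_that("build_strata composes classification and tri-partition consistently", {
  sim <- simulate_cells(small_config(seed = 3))
  reg <- synthetic_signature_registry()
  scores <- score_all(sim$matrix, reg)
  mal <- sim$annotation$obs_id[sim$annotation$cell_type == "malignant"]
  sub <- scores[scores$obs_id %in% mal, ]
  attr(sub, "obs_kind") <- "cell"
  class(sub) <- class(scores)
  strata <- build_strata(sub, sim$matrix, calibrate_thresholds(sub$sEMT))
  expect_equal(nrow(strata), length(mal))
  expect_false(anyNA(strata$emt_class))
  expect_false(anyNA(strata$mcam_class))
  expect_equal(as.character(strata$group_id), as.character(strata$emt_class))
})
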