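# Nonparametric comparisons and correlations.
#
# Exact two-tailed p-values are 2 x the smaller tail probability, capped at 1
# (the convention of the common statistics packages). The exact/approximate
# switch is recorded in every result so analyses are auditable:
#   - tie-free samples with combined n <= 25: exact via the null U /
#     signed-rank distributions;
#   - tied samples small enough to enumerate (n1+n2 <= 12 assignments for the
#     U test, n <= 14 sign patterns for the signed-rank test): exact by full
#     enumeration with midranks;
#   - otherwise: normal approximation with tie and continuity corrections.

comparison_result <- function(test, statistic, p, n1, n2, method) {
  # p lives in (0, 1]: cap the doubled tail at 1 and never underflow to 0
  p <- max(.Machine$double.xmin, min(1, unname(p)))
  structure(list(test = test, statistic = unname(statistic),
                 p_two_tailed = p, n1 = n1, n2 = n2,
                 method = method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, two-tailed p = %g (%s; n1 = %d, n2 = %d)\n",
              x$test, x$statistic, x$p_two_tailed, x$method, x$n1, x$n2))
  invisible(x)
}

#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The reported statistic is
#' the U of the first sample (ties handled by midranks).
#'
#' @param x,y numeric vectors (each non-empty).
#' @return a `comparison_result` with fields `test`, `statistic` (U),
#'   `p_two_tailed`, `n1`, `n2`, `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_two_tailed <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1 || length(y) < 1 || anyNA(c(x, y)))
    insufficient_data_error("both samples must be non-empty and free of NA")
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(pooled) > 0

  if (!ties && n1 + n2 <= 25) {
    p <- if (U > n1 * n2 / 2)
      stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    else stats::pwilcox(U, n1, n2)
    return(comparison_result("mann_whitney", U, 2 * p, n1, n2, "exact"))
  }
  if (ties && n1 + n2 <= 12) {
    sets <- utils::combn(n1 + n2, n1)
    base <- n1 * (n1 + 1) / 2
    us <- apply(sets, 2, function(idx) sum(r[idx]) - base)
    eps <- 1e-9
    p <- 2 * min(mean(us <= U + eps), mean(us >= U - eps))
    return(comparison_result("mann_whitney", U, p, n1, n2, "exact"))
  }
  n <- n1 + n2
  tie_tab <- table(r)
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  if (sigma2 <= 0)  # all values identical: no evidence against the null
    return(comparison_result("mann_whitney", U, 1, n1, n2, "normal_approx"))
  z <- U - n1 * n2 / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  comparison_result("mann_whitney", U, 2 * stats::pnorm(-abs(z)),
                    n1, n2, "normal_approx")
}

#' Two-tailed Wilcoxon matched-pairs signed-rank test
#'
#' Zero differences are dropped before ranking. The reported statistic is
#' W = min(W+, W-) over the nonzero differences.
#'
#' @param x,y paired numeric vectors of equal length (>= 2).
#' @return a `comparison_result` (statistic W).
#' @export
wilcoxon_paired_two_tailed <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    input_error("paired samples must have equal length")
  if (length(x) < 2 || anyNA(c(x, y)))
    insufficient_data_error("need >= 2 complete pairs")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    degenerate_data_error("all paired differences are zero")
  r <- rank(abs(d))
  wplus <- sum(r[d > 0])
  wtot <- n * (n + 1) / 2
  W <- min(wplus, wtot - wplus)
  ties <- anyDuplicated(abs(d)) > 0

  if (!ties && n <= 25) {
    p <- if (wplus > wtot / 2)
      stats::psignrank(wplus - 1, n, lower.tail = FALSE)
    else stats::psignrank(wplus, n)
    return(comparison_result("wilcoxon_paired", W, 2 * p, n, n, "exact"))
  }
  if (n <= 14) {  # full 2^n sign enumeration; exact even with tied |d|
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    ws <- as.numeric(signs %*% r)
    eps <- 1e-9
    p <- 2 * min(mean(ws <= wplus + eps), mean(ws >= wplus - eps))
    return(comparison_result("wilcoxon_paired", W, p, n, n, "exact"))
  }
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
  z <- wplus - wtot / 2
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  comparison_result("wilcoxon_paired", W, 2 * stats::pnorm(-abs(z)),
                    n, n, "normal_approx")
}

#' Spearman rank correlation with Fisher-z confidence interval
#'
#' Rank correlation with midranks for ties; two-tailed p from the t
#' approximation t = r * sqrt((n-2)/(1-r^2)); confidence interval from the
#' Fisher z transform, z +/- z_(1-alpha/2)/sqrt(n-3), back-transformed. At
#' r = +/-1 the Fisher z is infinite: the interval degenerates to [r, r] and
#' p is reported as the smallest representable positive double rather than 0.
#'
#' @param x,y numeric vectors of equal length, n >= 3 (n >= 4 for a CI;
#'   with n = 3 the CI is `NA`).
#' @param alpha two-sided CI level (default 0.05 for a 95% interval).
#' @return a `correlation_result`: list with `r`, `ci_low`, `ci_high`, `p`,
#'   `n`.
#' @export
spearman_with_ci <- function(x, y, alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) input_error("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) insufficient_data_error("Spearman correlation needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    undefined_correlation_error("correlation undefined for a constant variable")
  r <- stats::cor(rank(x), rank(y))
  if (abs(r) >= 1 - 1e-12) {
    r <- sign(r)
    return(structure(list(r = r, ci_low = r, ci_high = r,
                          p = .Machine$double.xmin, n = n),
                     class = "correlation_result"))
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  if (n >= 4) {
    z <- atanh(r)
    hw <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  } else ci <- c(NA_real_, NA_real_)
  structure(list(r = r, ci_low = ci[1], ci_high = ci[2],
                 p = min(1, p), n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman r = %.4f [%.4f, %.4f], p = %g (n = %d)\n",
              x$r, x$ci_low, x$ci_high, x$p, x$n))
  invisible(x)
}

#' Proportion of observations expressing a gene
#'
#' An observation "expresses" a gene when its value exceeds the detection
#' threshold (default 0, i.e. any nonzero value counts).
#'
#' @param matrix an [expression_matrix()].
#' @param gene gene symbol.
#' @param obs_subset optional character vector of observation ids (default:
#'   all observations).
#' @param detection_threshold expression cut-off (default 0).
#' @return list with `fraction`, `n_expressing`, `n_total`.
#' @export
proportion_expressing <- function(matrix, gene, obs_subset = NULL,
                                  detection_threshold = 0) {
  v <- gene_values(matrix, gene)
  if (!is.null(obs_subset)) {
    missing <- setdiff(obs_subset, names(v))
    if (length(missing) > 0)
      input_error(paste0("unknown observation ids in subset (first: ",
                         missing[1], ")"))
    v <- v[obs_subset]
  }
  if (length(v) == 0) insufficient_data_error("empty observation subset")
  k <- sum(v > detection_threshold)
  list(fraction = k / length(v), n_expressing = k, n_total = length(v))
}

#' Methylation table
#'
#' Probe-level M-values (log2 methylated/unmethylated intensity ratios,
#' unbounded reals) for samples labelled tumour or normal. The probe set is
#' identical across samples; genuinely unavailable measurements are `NA`,
#' never silently zero.
#'
#' @param M numeric matrix, samples x probes (NA allowed).
#' @param sample_id character vector of unique sample ids.
#' @param group `"tumour"` or `"normal"`, per sample.
#' @return object of class `methylation_table`.
#' @export
methylation_table <- function(M, sample_id, group) {
  if (!is.matrix(M)) input_error("M must be a samples x probes matrix")
  if (length(sample_id) != nrow(M) || length(group) != nrow(M))
    format_error("sample_id/group length must match the number of M rows")
  if (anyDuplicated(sample_id)) duplicate_id_error("duplicate sample ids")
  group <- as.character(group)
  if (!all(group %in% c("tumour", "normal")))
    validation_error("group must be 'tumour' or 'normal'")
  if (is.null(colnames(M))) colnames(M) <- paste0("probe", seq_len(ncol(M)))
  rownames(M) <- sample_id
  structure(list(M = M, sample_id = as.character(sample_id), group = group),
            class = "methylation_table")
}

#' Read a methylation TSV
#'
#' Columns: `sample_id`, `group`, then one column per probe. Empty cells or
#' `NA` mark unavailable probes.
#'
#' @param path file path.
#' @return a [methylation_table()].
#' @export
read_methylation_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(df)))
    format_error("methylation TSV needs 'sample_id' and 'group' columns")
  probes <- setdiff(colnames(df), c("sample_id", "group"))
  if (length(probes) == 0) format_error("methylation TSV has no probe columns")
  M <- as.matrix(df[, probes, drop = FALSE])
  if (!is.numeric(M)) format_error("probe columns must be numeric")
  methylation_table(M, df$sample_id, df$group)
}

#' Per-sample mean M-value
#'
#' Arithmetic mean over each sample's available (non-NA) probes. Samples with
#' no available probe are excluded with a warning.
#'
#' @param table a [methylation_table()].
#' @return data.frame with `sample_id`, `group`, `mean_M`, `n_probes`.
#' @export
methylation_mean_m <- function(table) {
  stopifnot(inherits(table, "methylation_table"))
  n_avail <- rowSums(!is.na(table$M))
  if (any(n_avail == 0)) {
    warning(sprintf("excluding %d sample(s) with no available probes",
                    sum(n_avail == 0)), call. = FALSE)
  }
  keep <- n_avail > 0
  data.frame(sample_id = table$sample_id[keep],
             group = table$group[keep],
             mean_M = rowMeans(table$M[keep, , drop = FALSE], na.rm = TRUE),
             n_probes = n_avail[keep],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare mean M-values between tumour and normal samples
#'
#' @param summary output of [methylation_mean_m()].
#' @return a `comparison_result` (two-tailed Mann-Whitney, tumour vs normal).
#' @export
methylation_group_test <- function(summary) {
  mann_whitney_two_tailed(summary$mean_M[summary$group == "tumour"],
                          summary$mean_M[summary$group == "normal"])
}

#' Correlate promoter methylation with matched expression
#'
#' Spearman correlation (with CI) between per-sample mean M-values and
#' matched expression values; samples without a match are dropped and
#' reported via a message.
#'
#' @param summary output of [methylation_mean_m()].
#' @param expression numeric vector of expression values named by sample id.
#' @return a `correlation_result`.
#' @export
methylation_expression_correlation <- function(summary, expression) {
  if (is.null(names(expression)))
    input_error("expression must be named by sample id")
  common <- intersect(summary$sample_id, names(expression))
  dropped <- length(summary$sample_id) - length(common)
  if (length(common) < 4)
    insufficient_data_error(sprintf(
      "only %d matched methylation/expression samples (need >= 4)",
      length(common)))
  if (dropped > 0)
    message(dropped, " methylation sample(s) had no matched expression value")
  m <- summary$mean_M[match(common, summary$sample_id)]
  spearman_with_ci(m, expression[common])
}
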