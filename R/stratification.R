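#' Stratification thresholds
#'
#' Score boundaries for the three EMT classes and the detection threshold for
#' "expressing" a gene. Cell-level defaults place the low/med boundary at 0
#' and the med/high boundary at 5 (log-normalised score units); bulk defaults
#' use 2000 and 5000 (linear scale). Intervals are half-open: low = score <
#' `emt_low_upper`; med = [`emt_low_upper`, `emt_high_lower`); high =
#' [`emt_high_lower`, Inf) — a real-valued score has no unclassifiable band.
#'
#' @param scale `"cell"` or `"bulk"`; selects the default boundaries.
#' @param emt_low_upper,emt_high_lower boundary overrides.
#' @param detection_threshold "expressing" means value strictly greater than
#'   this (default 0).
#' @return object of class `threshold_config`.
#' @export
threshold_config <- function(scale = c("cell", "bulk"),
                             emt_low_upper = NULL, emt_high_lower = NULL,
                             detection_threshold = 0) {
  scale <- match.arg(scale)
  defaults <- if (scale == "cell") c(0, 5) else c(2000, 5000)
  lo <- if (is.null(emt_low_upper)) defaults[1] else emt_low_upper
  hi <- if (is.null(emt_high_lower)) defaults[2] else emt_high_lower
  if (!(lo < hi))
    config_error("emt_low_upper must be strictly below emt_high_lower")
  structure(list(scale = scale, emt_low_upper = lo, emt_high_lower = hi,
                 detection_threshold = detection_threshold),
            class = "threshold_config")
}

#' Classify observations along the EMT spectrum
#'
#' Assigns each observation to the low, med or high EMT class from its sEMT
#' score using half-open intervals (see [threshold_config()]). Cell-scale
#' thresholds may only be applied to cell matrices and bulk thresholds to
#' bulk matrices, because the two scales differ by orders of magnitude; pass
#' `override_scale_check = TRUE` to apply thresholds across kinds knowingly.
#'
#' @param scores a `score_table` from [score_all()] with an `sEMT` column, or
#'   a plain named numeric vector of sEMT scores (no scale check possible).
#' @param thresholds a [threshold_config()].
#' @param override_scale_check disable the threshold-scale guard.
#' @return a `strata_table`: data.frame with `obs_id` and `emt_class`
#'   (ordered factor low < med < high).
#' @export
classify_emt <- function(scores, thresholds = threshold_config("cell"),
                         override_scale_check = FALSE) {
  stopifnot(inherits(thresholds, "threshold_config"))
  if (inherits(scores, "score_table")) {
    if (!"sEMT" %in% colnames(scores))
      input_error("score table has no sEMT column")
    kind <- attr(scores, "obs_kind")
    if (!override_scale_check && !is.null(kind)) {
      want <- if (thresholds$scale == "cell") "cell" else "bulk_sample"
      if (kind != want)
        config_error(sprintf(
          "%s-scale thresholds applied to a %s matrix; use matching thresholds or override_scale_check = TRUE",
          thresholds$scale, kind))
    }
    s <- scores$sEMT
    ids <- scores$obs_id
  } else {
    s <- as.numeric(scores)
    ids <- if (!is.null(names(scores))) names(scores) else as.character(seq_along(s))
  }
  cls <- cut(s, breaks = c(-Inf, thresholds$emt_low_upper,
                           thresholds$emt_high_lower, Inf),
             labels = c("low", "med", "high"), right = FALSE, ordered_result = TRUE)
  out <- data.frame(obs_id = ids, emt_class = cls, stringsAsFactors = FALSE)
  class(out) <- c("strata_table", "data.frame")
  out
}

#' Calibrate EMT boundaries from the score distribution
#'
#' The published class boundaries were set from the observed population
#' distribution; this helper reproduces that procedure by placing the
#' low/med and med/high boundaries at given quantiles of the sEMT scores
#' (defaults: 78th and 96th percentiles, the published class mass).
#'
#' @param semt numeric vector of sEMT scores.
#' @param probs two quantiles for the boundaries.
#' @param scale forwarded to [threshold_config()].
#' @param detection_threshold forwarded to [threshold_config()].
#' @return a [threshold_config()] with calibrated boundaries.
#' @export
calibrate_thresholds <- function(semt, probs = c(0.78, 0.96), scale = "cell",
                                 detection_threshold = 0) {
  q <- stats::quantile(semt, probs, names = FALSE)
  if (q[1] >= q[2])
    config_error("calibration quantiles give non-increasing boundaries")
  threshold_config(scale, emt_low_upper = q[1], emt_high_lower = q[2],
                   detection_threshold = detection_threshold)
}

#' Tri-partition observations by MCAM expression within groups
#'
#' Within each group (typically an EMT class): observations at or below the
#' detection threshold are MCAM-negative; the remaining expressers are sorted
#' by ascending expression (ties keep input order) and split into two
#' equal-sized halves, MCAM-low then MCAM-high; with an odd number of
#' expressers the extra observation joins the low group. Hence per group
#' |low| - |high| is 0 or 1.
#'
#' @param expr numeric vector of MCAM expression values, optionally named by
#'   observation id.
#' @param group_ids vector of group labels, same length as `expr`.
#' @param detection_threshold expressing means value strictly above this
#'   (default 0).
#' @return a `strata_table` data.frame with `obs_id`, `group_id` and
#'   `mcam_class` (factor neg/low/high).
#' @export
mcam_tripartition <- function(expr, group_ids, detection_threshold = 0) {
  expr <- as.numeric(expr)
  if (length(expr) != length(group_ids))
    input_error("expr and group_ids must have equal length")
  ids <- if (!is.null(names(expr))) names(expr) else as.character(seq_along(expr))
  cls <- rep(NA_character_, length(expr))
  for (g in unique(group_ids)) {
    idx <- which(group_ids == g)
    if (length(idx) == 0) next
    neg <- idx[expr[idx] <= detection_threshold]
    pos <- idx[expr[idx] > detection_threshold]
    cls[neg] <- "neg"
    k <- length(pos)
    if (k > 0) {
      ord <- pos[order(expr[pos])]  # stable: ties keep input order
      n_low <- ceiling(k / 2)
      cls[ord[seq_len(n_low)]] <- "low"
      if (k > n_low) cls[ord[(n_low + 1):k]] <- "high"
    }
  }
  out <- data.frame(obs_id = ids, group_id = as.character(group_ids),
                    mcam_class = factor(cls, levels = c("neg", "low", "high")),
                    stringsAsFactors = FALSE)
  class(out) <- c("strata_table", "data.frame")
  out
}

#' Build the combined strata table
#'
#' Convenience wrapper: classifies sEMT, then tri-partitions MCAM expression
#' within each EMT class (or any other grouping column supplied).
#'
#' @param scores a `score_table` with an `sEMT` column.
#' @param matrix the [expression_matrix()] the scores came from (for MCAM).
#' @param thresholds a [threshold_config()].
#' @param gene partition gene (default `"MCAM"`).
#' @param group_by `"emt_class"` (default) or the name of a column in
#'   `annotation`.
#' @param annotation optional [obs_annotation()] providing alternative
#'   grouping columns.
#' @param override_scale_check forwarded to [classify_emt()].
#' @return data.frame with `obs_id`, `emt_class`, `group_id`, `mcam_class`.
#' @export
build_strata <- function(scores, matrix, thresholds = threshold_config("cell"),
                         gene = "MCAM", group_by = "emt_class",
                         annotation = NULL, override_scale_check = FALSE) {
  emt <- classify_emt(scores, thresholds, override_scale_check)
  expr <- gene_values(matrix, gene)[emt$obs_id]
  groups <- if (group_by == "emt_class") {
    as.character(emt$emt_class)
  } else {
    if (is.null(annotation) || !group_by %in% colnames(annotation))
      config_error(paste0("grouping column '", group_by,
                          "' requires an annotation providing it"))
    as.character(annotation[[group_by]][match(emt$obs_id, annotation$obs_id)])
  }
  tri <- mcam_tripartition(expr, groups, thresholds$detection_threshold)
  out <- data.frame(obs_id = emt$obs_id, emt_class = emt$emt_class,
                    group_id = tri$group_id, mcam_class = tri$mcam_class,
                    stringsAsFactors = FALSE)
  class(out) <- c("strata_table", "data.frame")
  out
}

#' Nine-subpopulation summary
#'
#' Cross-tabulates EMT class against MCAM class and reports, per cell of the
#' 3 x 3 table, the number of observations and the arithmetic means of the
#' invasion (sInv) and stemness (sCSC) scores. Empty combinations are kept
#' with n = 0 and undefined (NA) means.
#'
#' @param strata data.frame with `obs_id`, `emt_class`, `mcam_class`.
#' @param scores a `score_table` (or data.frame) with `obs_id`, `sInv`,
#'   `sCSC`.
#' @return a `subpopulation_summary` data.frame with columns `emt_class`,
#'   `mcam_class`, `n`, `mean_sInv`, `mean_sCSC` (nine rows).
#' @export
cross_tabulate <- function(strata, scores) {
  need <- c("sInv", "sCSC")
  if (!all(need %in% colnames(scores)))
    input_error("scores must contain sInv and sCSC columns")
  m <- match(strata$obs_id, scores$obs_id)
  if (anyNA(m)) input_error("every stratified observation needs scores")
  if (anyNA(strata$emt_class) || anyNA(strata$mcam_class))
    input_error("every observation needs both emt_class and mcam_class labels")
  emt <- factor(strata$emt_class, levels = c("low", "med", "high"))
  mc <- factor(strata$mcam_class, levels = c("neg", "low", "high"))
  grid <- expand.grid(emt_class = levels(emt), mcam_class = levels(mc),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- interaction(emt, mc, drop = FALSE)
  sinv <- scores$sInv[m]; scsc <- scores$sCSC[m]
  agg <- function(v) tapply(v, key, mean)
  counts <- table(key)
  gk <- paste(grid$emt_class, grid$mcam_class, sep = ".")
  out <- data.frame(grid,
                    n = as.integer(counts[gk]),
                    mean_sInv = as.numeric(agg(sinv)[gk]),
                    mean_sCSC = as.numeric(agg(scsc)[gk]),
                    stringsAsFactors = FALSE)
  class(out) <- c("subpopulation_summary", "data.frame")
  out
}

#' Correlation of subpopulation mean scores
#'
#' Spearman correlation (with Fisher-z CI) between the mean invasion and mean
#' stemness scores across the defined rows of a nine-subpopulation summary.
#'
#' @param summary a [cross_tabulate()] result.
#' @return a `correlation_result`.
#' @export
subpopulation_correlation <- function(summary) {
  ok <- summary$n > 0 & !is.na(summary$mean_sInv) & !is.na(summary$mean_sCSC)
  if (sum(ok) < 3)
    insufficient_data_error(sprintf(
      "only %d subpopulations with defined means (need >= 3)", sum(ok)))
  spearman_with_ci(summary$mean_sInv[ok], summary$mean_sCSC[ok])
}

#' Gene expression across EMT strata
#'
#' Splits a gene's expression values by EMT class and performs the three
#' pairwise two-tailed Mann-Whitney comparisons (low-med, med-high,
#' low-high).
#'
#' @param matrix an [expression_matrix()].
#' @param gene gene symbol.
#' @param strata data.frame with `obs_id` and `emt_class`.
#' @return list with `values` (list of numeric vectors named low/med/high),
#'   `n` (per-class counts) and `comparisons` (data.frame: group1, group2, U,
#'   p_two_tailed, method).
#' @export
expression_by_stratum <- function(matrix, gene, strata) {
  v <- gene_values(matrix, gene)
  missing <- setdiff(strata$obs_id, names(v))
  if (length(missing) > 0)
    input_error("strata contain observations absent from the matrix")
  cls <- factor(strata$emt_class, levels = c("low", "med", "high"))
  vals <- split(unname(v[strata$obs_id]), cls)
  pairs <- list(c("low", "med"), c("med", "high"), c("low", "high"))
  comp <- do.call(rbind, lapply(pairs, function(p) {
    a <- vals[[p[1]]]; b <- vals[[p[2]]]
    if (length(a) == 0 || length(b) == 0)
      return(data.frame(group1 = p[1], group2 = p[2], U = NA_real_,
                        p_two_tailed = NA_real_, method = NA_character_))
    res <- mann_whitney_two_tailed(a, b)
    data.frame(group1 = p[1], group2 = p[2], U = res$statistic,
               p_two_tailed = res$p_two_tailed, method = res$method,
               stringsAsFactors = FALSE)
  }))
  list(values = vals, n = vapply(vals, length, integer(1)), comparisons = comp)
}
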