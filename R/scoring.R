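#' Score one signature on an expression matrix
#'
#' Computes the per-observation signature score. For `sum_difference`
#' signatures the score is the summed expression of the positive (mesenchymal)
#' set minus the summed expression of the negative (epithelial) set; for
#' `mean` signatures it is the arithmetic mean over the signature genes
#' present in the matrix.
#'
#' Missing-gene policy differs by aggregation, deliberately: a mean over the
#' present genes keeps its scale when a panel lacks a gene, so mean signatures
#' tolerate absentees (with a warning, and the absentees recorded); a
#' sum-difference score shifts against its fixed classification thresholds if
#' any of its twelve terms is dropped, so missing genes are an error unless
#' `allow_missing = TRUE` is given explicitly.
#'
#' @param matrix an [expression_matrix()].
#' @param signature a [gene_signature()].
#' @param allow_missing permit scoring a `sum_difference` signature with
#'   absent genes (treated as contributing zero). Default `FALSE`.
#' @return numeric vector of scores named by observation id, with attributes
#'   `n_genes_used` and `missing_genes`.
#' @export
score_signature <- function(matrix, signature, allow_missing = FALSE) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(signature, "gene_signature"))
  if (anyDuplicated(matrix$gene_ids))
    duplicate_id_error("matrix has duplicated gene columns; refusing to score")
  sig_genes <- c(signature$positive_set, signature$negative_set)
  present <- sig_genes[sig_genes %in% matrix$gene_ids]
  absent <- setdiff(sig_genes, present)

  if (signature$aggregation == "sum_difference") {
    if (length(absent) > 0 && !allow_missing)
      missing_gene_error(paste0(
        "signature '", signature$name, "' genes missing from matrix: ",
        paste(absent, collapse = ", ")))
    pos <- intersect(signature$positive_set, present)
    neg <- intersect(signature$negative_set, present)
    score <- row_sum(matrix$values, pos) - row_sum(matrix$values, neg)
  } else {
    pos <- intersect(signature$positive_set, present)
    if (length(pos) == 0)
      missing_gene_error(paste0("no genes of mean signature '", signature$name,
                                "' are present in the matrix"))
    if (length(absent) > 0)
      warning(sprintf("signature '%s': averaging over %d/%d genes (missing: %s)",
                      signature$name, length(pos), length(sig_genes),
                      paste(absent, collapse = ", ")), call. = FALSE)
    score <- row_sum(matrix$values, pos) / length(pos)
  }
  names(score) <- matrix$obs_ids
  attr(score, "n_genes_used") <- length(present)
  attr(score, "missing_genes") <- absent
  score
}

row_sum <- function(values, genes) {
  if (length(genes) == 0) return(numeric(nrow(values)))
  sub <- values[, genes, drop = FALSE]
  as.numeric(if (inherits(sub, "Matrix")) Matrix::rowSums(sub) else rowSums(sub))
}

#' Score every registered signature
#'
#' @param matrix an [expression_matrix()].
#' @param registry a [signature_registry()].
#' @param allow_missing passed to [score_signature()].
#' @return a `score_table`: data.frame with `obs_id` and one column per
#'   signature, carrying attributes `scale`, `obs_kind` (from the matrix) and
#'   `metadata` (per-signature genes used / missing).
#' @export
score_all <- function(matrix, registry, allow_missing = FALSE) {
  stopifnot(inherits(registry, "signature_registry"))
  if (length(registry) == 0) input_error("signature registry is empty")
  cols <- list()
  meta <- list()
  for (nm in names(registry)) {
    s <- tryCatch(score_signature(matrix, registry[[nm]], allow_missing),
                  emtstrat_error = function(e) abort_emt(
                    paste0("scoring '", nm, "': ", conditionMessage(e)),
                    class(e)[1]))
    meta[[nm]] <- list(n_genes_used = attr(s, "n_genes_used"),
                       missing_genes = attr(s, "missing_genes"),
                       aggregation = registry[[nm]]$aggregation)
    cols[[nm]] <- as.numeric(s)
  }
  out <- data.frame(obs_id = matrix$obs_ids, cols, check.names = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "scale") <- matrix$scale
  attr(out, "obs_kind") <- matrix$obs_kind
  attr(out, "metadata") <- meta
  class(out) <- c("score_table", "data.frame")
  out
}
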