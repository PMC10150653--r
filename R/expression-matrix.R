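#' Expression matrix container
#'
#' An `expression_matrix` holds non-negative expression values for a set of
#' observations (single cells or bulk samples) by gene, together with a
#' declared measurement scale. The scale is never inferred from the values:
#' cell-level log-normalised data and linear bulk data carry different
#' stratification thresholds, so silent inference would misclassify
#' observations.
#'
#' @param values numeric matrix (observations in rows, genes in columns) or a
#'   `Matrix` sparse matrix; all entries must be non-negative and non-missing.
#'   In sparse inputs, absent entries mean zero expression.
#' @param obs_ids character vector of unique observation identifiers (rows).
#' @param gene_ids character vector of gene symbols (columns); normalised via
#'   [normalize_gene_symbols()] and required to be unique afterwards.
#' @param scale `"log_normalized"` or `"linear"`.
#' @param obs_kind `"cell"` or `"bulk_sample"`.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `obs_ids`, `gene_ids`, `scale`, `obs_kind`.
#' @export
expression_matrix <- function(values, obs_ids, gene_ids,
                              scale = c("log_normalized", "linear"),
                              obs_kind = c("cell", "bulk_sample")) {
  scale <- match.arg(scale)
  obs_kind <- match.arg(obs_kind)
  if (!(is.matrix(values) || inherits(values, "Matrix")))
    input_error("`values` must be a base matrix or a Matrix sparse matrix")
  obs_ids <- as.character(obs_ids)
  if (length(obs_ids) != nrow(values) || length(gene_ids) != ncol(values))
    format_error(sprintf(
      "dimension mismatch: %d x %d values but %d obs ids and %d gene ids",
      nrow(values), ncol(values), length(obs_ids), length(gene_ids)))
  gene_ids <- normalize_gene_symbols(gene_ids)
  if (anyDuplicated(obs_ids)) {
    dup <- unique(obs_ids[duplicated(obs_ids)])
    duplicate_id_error(paste0("duplicate observation ids: ",
                              paste(utils::head(dup, 10), collapse = ", ")))
  }
  vals <- if (inherits(values, "Matrix")) values@x else values
  if (anyNA(vals)) format_error("expression values contain missing entries")
  if (any(vals < 0)) format_error("expression values must be non-negative")
  dimnames(values) <- list(obs_ids, as.character(gene_ids))
  structure(
    list(values = values, obs_ids = obs_ids,
         gene_ids = as.character(gene_ids), scale = scale, obs_kind = obs_kind),
    class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d %s x %d genes [%s]\n",
              nrow(x$values),
              if (x$obs_kind == "cell") "cells" else "bulk samples",
              ncol(x$values), x$scale))
  invisible(x)
}

#' Extract expression values for one gene
#'
#' @param x an [expression_matrix()].
#' @param gene gene symbol (normalised before lookup).
#' @return numeric vector named by observation id.
#' @export
gene_values <- function(x, gene) {
  stopifnot(inherits(x, "expression_matrix"))
  g <- normalize_gene_symbols(gene)
  if (!g %in% x$gene_ids)
    missing_gene_error(paste0("gene not present in matrix: ", g))
  v <- as.numeric(x$values[, g])
  names(v) <- x$obs_ids
  v
}

#' Read a MatrixMarket triplet expression matrix
#'
#' Reads a MatrixMarket coordinate file (rows = observations) together with
#' one-column observation-id and gene-id files, as exported by single-cell
#' portals and by [write_mtx_triplet()].
#'
#' @param matrix_path path to the `.mtx` coordinate file.
#' @param obs_path path to a one-id-per-line observation id file.
#' @param gene_path path to a one-symbol-per-line gene id file.
#' @inheritParams expression_matrix
#' @return an [expression_matrix()] (sparse-backed).
#' @export
read_mtx_triplet <- function(matrix_path, obs_path, gene_path,
                             scale = c("log_normalized", "linear"),
                             obs_kind = c("cell", "bulk_sample")) {
  m <- tryCatch(Matrix::readMM(matrix_path),
                error = function(e) format_error(
                  paste0("cannot parse MatrixMarket file '", matrix_path, "': ",
                         conditionMessage(e))))
  obs <- readLines(obs_path)
  genes <- readLines(gene_path)
  obs <- obs[nzchar(obs)]
  genes <- genes[nzchar(genes)]
  if (length(obs) != nrow(m))
    format_error(sprintf(
      "matrix declares %d rows but obs file '%s' has %d ids",
      nrow(m), obs_path, length(obs)))
  if (length(genes) != ncol(m))
    format_error(sprintf(
      "matrix declares %d columns but gene file '%s' has %d ids",
      ncol(m), gene_path, length(genes)))
  expression_matrix(methods::as(m, "CsparseMatrix"), obs, genes,
                    scale = scale, obs_kind = obs_kind)
}

#' Write a MatrixMarket triplet expression matrix
#'
#' @param x an [expression_matrix()].
#' @param matrix_path,obs_path,gene_path output paths (see
#'   [read_mtx_triplet()]).
#' @return invisibly, the three paths.
#' @export
write_mtx_triplet <- function(x, matrix_path, obs_path, gene_path) {
  stopifnot(inherits(x, "expression_matrix"))
  m <- methods::as(Matrix::Matrix(x$values, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(m, matrix_path)
  writeLines(x$obs_ids, obs_path)
  writeLines(x$gene_ids, gene_path)
  invisible(c(matrix_path, obs_path, gene_path))
}

#' Read a dense TSV expression matrix
#'
#' Expects a header row of gene symbols and a first column of observation
#' ids. Any non-numeric or missing cell is a format error reported with its
#' row and column.
#'
#' @param path path to the TSV file.
#' @inheritParams expression_matrix
#' @return an [expression_matrix()] (dense).
#' @export
read_dense_tsv <- function(path,
                           scale = c("log_normalized", "linear"),
                           obs_kind = c("cell", "bulk_sample")) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", sep = "\t")
  if (ncol(raw) < 2) format_error("dense TSV needs an id column and >=1 gene column")
  obs <- raw[[1]]
  genes <- colnames(raw)[-1]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(cells), nrow = nrow(cells)))
  bad <- which(is.na(num) | cells == "NA", arr.ind = TRUE)
  if (nrow(bad) > 0) {
    b <- bad[1, ]
    format_error(sprintf(
      "non-numeric value '%s' at row %d (obs '%s'), column '%s' of %s",
      cells[b[1], b[2]], b[1], obs[b[1]], genes[b[2]], path))
  }
  expression_matrix(num, obs, genes, scale = scale, obs_kind = obs_kind)
}

#' Write a dense TSV expression matrix
#'
#' @param x an [expression_matrix()].
#' @param path output path.
#' @param digits significant digits to write (default 10, ample for a
#'   value-exact round trip at 6 significant digits).
#' @return invisibly, `path`.
#' @export
write_dense_tsv <- function(x, path, digits = 10) {
  stopifnot(inherits(x, "expression_matrix"))
  v <- as.matrix(x$values)
  df <- data.frame(obs_id = x$obs_ids,
                   signif(v, digits),
                   check.names = FALSE)
  colnames(df) <- c("obs_id", x$gene_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Observation annotations
#'
#' Validates a per-observation annotation table against an expression matrix:
#' every observation must have exactly one row, with a recognised cell type.
#'
#' @param obs_id,patient_id,cell_type,subtype vectors of equal length;
#'   `cell_type` must be one of malignant, normal_epithelial, endothelial,
#'   perivascular, CAF, immune, other.
#' @return a `data.frame` of class `obs_annotation`.
#' @export
obs_annotation <- function(obs_id, patient_id, cell_type,
                           subtype = NA_character_) {
  types <- c("malignant", "normal_epithelial", "endothelial", "perivascular",
             "CAF", "immune", "other")
  cell_type <- as.character(cell_type)
  if (!all(cell_type %in% types))
    validation_error(paste0("unknown cell_type: ",
                            paste(unique(setdiff(cell_type, types)), collapse = ", ")))
  if (anyDuplicated(obs_id))
    duplicate_id_error("annotation has duplicated obs_id rows")
  out <- data.frame(obs_id = as.character(obs_id),
                    patient_id = as.character(patient_id),
                    cell_type = cell_type,
                    subtype = as.character(subtype),
                    stringsAsFactors = FALSE)
  class(out) <- c("obs_annotation", "data.frame")
  out
}

#' Check that an annotation covers a matrix
#'
#' @param matrix an [expression_matrix()].
#' @param annotation an [obs_annotation()].
#' @return invisibly `TRUE`; errors if any observation lacks an annotation.
#' @export
validate_annotation <- function(matrix, annotation) {
  missing <- setdiff(matrix$obs_ids, annotation$obs_id)
  if (length(missing) > 0)
    validation_error(paste0(length(missing),
                            " observations lack an annotation row (first: ",
                            missing[1], ")"))
  invisible(TRUE)
}
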