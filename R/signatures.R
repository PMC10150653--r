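#' Normalise gene symbols
#'
#' Upper-cases and whitespace-strips raw gene identifiers. No alias or HGNC
#' resolution is attempted: signatures and matrices are matched on plain
#' symbols, so a hidden alias table could silently change which genes enter a
#' score. A mapping of changed symbols is attached for logging.
#'
#' @param gene_ids character vector of raw identifiers.
#' @return normalised character vector with an attribute `mapping`, a
#'   data.frame of `(old, new)` pairs for identifiers that changed.
#' @export
normalize_gene_symbols <- function(gene_ids) {
  old <- as.character(gene_ids)
  new <- toupper(trimws(old))
  if (anyDuplicated(new)) {
    dup <- unique(new[duplicated(new)])
    duplicate_id_error(paste0(
      "gene symbols collide after normalisation: ",
      paste(utils::head(dup, 10), collapse = ", ")))
  }
  changed <- which(old != new)
  attr(new, "mapping") <- data.frame(old = old[changed], new = new[changed],
                                     stringsAsFactors = FALSE)
  new
}

#' Gene signature
#'
#' A named gene set with an aggregation rule. `sum_difference` signatures
#' (the EMT score) subtract the summed expression of the `negative_set`
#' (epithelial markers) from the summed expression of the `positive_set`
#' (mesenchymal markers); `mean` signatures (invasion, stemness,
#' angiogenesis) average the `positive_set`.
#'
#' @param name signature name (e.g. `"sEMT"`).
#' @param positive_set gene symbols contributing positively.
#' @param negative_set gene symbols contributing negatively (empty for mean
#'   signatures).
#' @param aggregation `"sum_difference"` or `"mean"`.
#' @return an object of class `gene_signature`.
#' @export
gene_signature <- function(name, positive_set, negative_set = character(),
                           aggregation = c("mean", "sum_difference")) {
  aggregation <- match.arg(aggregation)
  positive_set <- normalize_gene_symbols(positive_set)
  negative_set <- if (length(negative_set)) normalize_gene_symbols(negative_set) else character()
  both <- intersect(positive_set, negative_set)
  if (length(both) > 0)
    validation_error(paste0("signature '", name, "' lists genes in both roles: ",
                            paste(both, collapse = ", ")))
  if (aggregation == "sum_difference") {
    if (length(positive_set) == 0 || length(negative_set) == 0)
      validation_error(paste0("sum_difference signature '", name,
                              "' needs non-empty positive and negative sets"))
  } else {
    if (length(positive_set) == 0)
      validation_error(paste0("mean signature '", name, "' is empty"))
    if (length(negative_set) > 0)
      validation_error(paste0("mean signature '", name,
                              "' must not have a negative set"))
  }
  structure(list(name = name, aggregation = aggregation,
                 positive_set = as.character(positive_set),
                 negative_set = as.character(negative_set)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s [%s] +%d/-%d genes\n", x$name,
              x$aggregation, length(x$positive_set), length(x$negative_set)))
  invisible(x)
}

# Twelve-gene EMT score of the breast-cancer analysis: sum of six mesenchymal
# marker expressions minus sum of six epithelial marker expressions.
EMT_EPITHELIAL_GENES  <- c("CDH1", "GRHL2", "ITGB4", "KRT5", "KRT8", "FST")
EMT_MESENCHYMAL_GENES <- c("CDH2", "ZEB1", "VIM", "MMP1", "FN1", "TGFB1I1")

#' Built-in sEMT signature
#'
#' Mesenchymal-positive sum-difference signature over the twelve canonical
#' EMT marker genes (higher score = more mesenchymal).
#' @return a [gene_signature()].
#' @export
semt_signature <- function() {
  gene_signature("sEMT",
                 positive_set = EMT_MESENCHYMAL_GENES,
                 negative_set = EMT_EPITHELIAL_GENES,
                 aggregation = "sum_difference")
}

#' Signature registry
#'
#' A named collection of [gene_signature()] objects. The default registry
#' ships the built-in sEMT signature; invasion (sInv), stemness (sCSC) and
#' angiogenesis (sAng) gene lists are study-specific and are loaded from a
#' signature file (see [read_signature_file()]).
#'
#' @param ... `gene_signature` objects.
#' @param include_semt include the built-in sEMT signature (default `TRUE`).
#' @return an object of class `signature_registry` (named list).
#' @export
signature_registry <- function(..., include_semt = TRUE) {
  sigs <- list(...)
  if (include_semt) sigs <- c(list(semt_signature()), sigs)
  ok <- vapply(sigs, inherits, logical(1), "gene_signature")
  if (!all(ok)) input_error("all registry entries must be gene_signature objects")
  names(sigs) <- vapply(sigs, `[[`, character(1), "name")
  if (anyDuplicated(names(sigs)))
    duplicate_id_error(paste0("duplicate signature names: ",
                              paste(unique(names(sigs)[duplicated(names(sigs))]),
                                    collapse = ", ")))
  structure(sigs, class = "signature_registry")
}

#' Add a signature to a registry
#' @param registry a [signature_registry()].
#' @param signature a [gene_signature()].
#' @return the extended registry.
#' @export
register_signature <- function(registry, signature) {
  stopifnot(inherits(registry, "signature_registry"),
            inherits(signature, "gene_signature"))
  if (signature$name %in% names(registry))
    duplicate_id_error(paste0("signature already registered: ", signature$name))
  out <- c(unclass(registry), stats::setNames(list(signature), signature$name))
  structure(out, class = "signature_registry")
}

#' Report genes shared between signatures
#'
#' Lists every gene appearing in more than one registered signature. In the
#' default breast-cancer signature set the expectation is that MMP1 (shared
#' by sEMT and sCSC) is the only such gene.
#'
#' @param registry a [signature_registry()].
#' @return data.frame with columns `gene` and `signatures`
#'   (comma-separated names); zero rows when signatures are disjoint.
#' @export
signature_overlap <- function(registry) {
  stopifnot(inherits(registry, "signature_registry"))
  memb <- lapply(registry, function(s) unique(c(s$positive_set, s$negative_set)))
  genes <- unlist(memb, use.names = FALSE)
  tab <- table(genes)
  shared <- names(tab)[tab > 1]
  data.frame(
    gene = shared,
    signatures = vapply(shared, function(g)
      paste(names(registry)[vapply(memb, function(m) g %in% m, logical(1))],
            collapse = ","), character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Read signatures from a TSV file
#'
#' The file must have columns `signature_name`, `gene`, `set_role`
#' (`positive` or `negative`). Aggregation is inferred per signature:
#' `sum_difference` if it has any negative rows, otherwise `mean`. Parsing is
#' row-order independent.
#'
#' @param path path to the signature TSV.
#' @param registry optional existing [signature_registry()] to extend;
#'   by default a new registry containing the built-in sEMT is created
#'   (unless the file itself defines `sEMT`, which then replaces it).
#' @return a [signature_registry()].
#' @export
read_signature_file <- function(path, registry = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("signature_name", "gene", "set_role")
  if (!all(need %in% colnames(df)))
    format_error(paste0("signature file must have columns ",
                        paste(need, collapse = ", ")))
  if (!all(df$set_role %in% c("positive", "negative")))
    format_error("set_role must be 'positive' or 'negative'")
  if (nrow(df) == 0) validation_error("signature file has no rows")
  sigs <- lapply(split(df, df$signature_name), function(d) {
    pos <- d$gene[d$set_role == "positive"]
    neg <- d$gene[d$set_role == "negative"]
    agg <- if (length(neg) > 0) "sum_difference" else "mean"
    gene_signature(d$signature_name[1], positive_set = pos,
                   negative_set = neg, aggregation = agg)
  })
  if (is.null(registry))
    registry <- signature_registry(include_semt = !"sEMT" %in% names(sigs))
  for (s in sigs) registry <- register_signature(registry, s)
  registry
}

#' Path to the bundled synthetic signature file
#'
#' The invasion/stemness/angiogenesis gene lists of the original study live
#' in its supplement and are not redistributed here. This bundled file is a
#' synthetic stand-in with the same structure: a 10-gene invasion signature,
#' a 20-gene stemness signature sharing MMP1 with sEMT (the only
#' cross-signature gene), and a 10-gene angiogenesis signature anchored on
#' the endothelial/perivascular markers KDR and CSPG4. It matches the genes
#' produced by [simulate_cells()] and [simulate_bulk()].
#'
#' @return file path.
#' @export
synthetic_signature_path <- function() {
  system.file("extdata", "signatures_synthetic.tsv", package = "emtstrat",
              mustWork = TRUE)
}

#' Registry of built-in sEMT plus the bundled synthetic signatures
#' @return a [signature_registry()] with sEMT, sInv, sCSC and sAng.
#' @export
synthetic_signature_registry <- function() {
  read_signature_file(synthetic_signature_path())
}
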