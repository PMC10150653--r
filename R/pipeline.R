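#' Run the scoring / stratification pipeline end to end
#'
#' Orchestrates: obtain an expression matrix (simulated, or read from MTX
#' triplet / dense TSV), score all registered signatures, classify the EMT
#' spectrum, tri-partition MCAM within each class, build the
#' nine-subpopulation summary and its correlation, and write diff-able TSV
#' outputs plus a JSON run summary. Re-running with the same config and seed
#' reproduces identical outputs.
#'
#' The config is a named list (or path to a YAML file with the same shape):
#' \describe{
#'   \item{seed}{integer; seeds the simulation.}
#'   \item{outdir}{output directory (created if needed).}
#'   \item{simulate}{optional list of [synthetic_config()] overrides; when
#'     present, cells are simulated and only malignant cells are stratified.}
#'   \item{input}{alternative to `simulate`: list with `format`
#'     (`"mtx"`/`"tsv"`), `matrix` (+ `obs`, `genes` for mtx), `scale`,
#'     `obs_kind`, optional `annotation` TSV (obs_id, patient_id, cell_type,
#'     subtype) and optional `stratify_cell_type` (default `"malignant"`).}
#'   \item{signatures}{optional signature TSV path; defaults to the bundled
#'     synthetic signatures when simulating, else the built-in sEMT only.}
#'   \item{thresholds}{list: `scale` (`"cell"`/`"bulk"`), optional
#'     `emt_low_upper`, `emt_high_lower`, `detection_threshold`, and
#'     `calibrate` (logical; percentile-calibrate boundaries from the score
#'     distribution, default `FALSE`).}
#'   \item{group_by}{grouping for the MCAM tri-partition (default
#'     `"emt_class"`).}
#'   \item{allow_missing}{passed to [score_all()].}
#' }
#'
#' @param config named list or YAML path.
#' @return invisibly, the run summary (also written as
#'   `run_summary.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) config_error("config must be a list or a YAML path")
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% config_error("config needs an 'outdir'")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- "load"
  res <- tryCatch({
    # --- inputs ------------------------------------------------------------
    annotation <- NULL
    simulated <- !is.null(config$simulate)
    if (simulated) {
      sim_args <- config$simulate
      sim_args$seed <- seed
      scfg <- do.call(synthetic_config, sim_args)
      sim <- simulate_cells(scfg)
      matrix <- sim$matrix
      annotation <- sim$annotation
    } else if (!is.null(config$input)) {
      inp <- config$input
      fmt <- inp$format %||% "mtx"
      scl <- inp$scale %||% "log_normalized"
      kind <- inp$obs_kind %||% "cell"
      matrix <- if (fmt == "mtx") {
        read_mtx_triplet(inp$matrix, inp$obs, inp$genes, scl, kind)
      } else if (fmt == "tsv") {
        read_dense_tsv(inp$matrix, scl, kind)
      } else config_error(paste0("unknown input format: ", fmt))
      if (!is.null(inp$annotation)) {
        a <- utils::read.delim(inp$annotation, sep = "\t",
                               colClasses = "character")
        annotation <- obs_annotation(a$obs_id, a$patient_id, a$cell_type,
                                     a$subtype %||% NA_character_)
        validate_annotation(matrix, annotation)
      }
    } else config_error("config needs a 'simulate' or an 'input' block")

    registry <- if (!is.null(config$signatures)) {
      read_signature_file(config$signatures)
    } else if (simulated) synthetic_signature_registry() else signature_registry()

    # --- scoring -----------------------------------------------------------
    stage <- "score"
    scores <- score_all(matrix, registry, isTRUE(config$allow_missing))

    # stratify malignant cells when an annotation identifies them
    strat_type <- (config$input$stratify_cell_type %||% "malignant")
    strat_ids <- if (!is.null(annotation) && strat_type %in% annotation$cell_type) {
      annotation$obs_id[annotation$cell_type == strat_type]
    } else matrix$obs_ids
    sub_scores <- scores[scores$obs_id %in% strat_ids, , drop = FALSE]
    for (a in c("scale", "obs_kind", "metadata"))
      attr(sub_scores, a) <- attr(scores, a)
    class(sub_scores) <- class(scores)

    # --- stratification ----------------------------------------------------
    stage <- "stratify"
    thr_cfg <- config$thresholds %||% list()
    thr_scale <- thr_cfg$scale %||%
      (if (matrix$obs_kind == "cell") "cell" else "bulk")
    thresholds <- if (isTRUE(thr_cfg$calibrate)) {
      calibrate_thresholds(sub_scores$sEMT, scale = thr_scale,
                           detection_threshold = thr_cfg$detection_threshold %||% 0)
    } else {
      threshold_config(thr_scale,
                       emt_low_upper = thr_cfg$emt_low_upper,
                       emt_high_lower = thr_cfg$emt_high_lower,
                       detection_threshold = thr_cfg$detection_threshold %||% 0)
    }
    strata <- build_strata(sub_scores, matrix, thresholds,
                           group_by = config$group_by %||% "emt_class",
                           annotation = annotation)

    # --- report ------------------------------------------------------------
    stage <- "report"
    have_inv <- all(c("sInv", "sCSC") %in% colnames(sub_scores))
    subpops <- if (have_inv) cross_tabulate(strata, sub_scores) else NULL
    subpop_cor <- if (have_inv)
      tryCatch(unclass(subpopulation_correlation(subpops)),
               emtstrat_error = function(e) conditionMessage(e)) else NULL
    mcam_prop <- tryCatch(
      proportion_expressing(matrix, "MCAM", strat_ids,
                            thresholds$detection_threshold),
      emtstrat_error = function(e) NULL)

    stage <- "write"
    utils::write.table(scores, file.path(outdir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(strata, file.path(outdir, "strata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(subpops))
      utils::write.table(subpops, file.path(outdir, "subpops.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    stats_out <- list(subpopulation_correlation = subpop_cor,
                      mcam_proportion_expressing = mcam_prop)
    jsonlite::write_json(stats_out, file.path(outdir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)

    summary <- list(
      seed = seed,
      scale = matrix$scale,
      obs_kind = matrix$obs_kind,
      n_obs_total = nrow(matrix$values),
      n_obs_scored = nrow(scores),
      n_obs_stratified = nrow(strata),
      thresholds = unclass(thresholds),
      signatures = lapply(registry, function(s)
        list(aggregation = s$aggregation, positive_set = s$positive_set,
             negative_set = s$negative_set)),
      signature_metadata = attr(scores, "metadata"),
      signature_overlap = signature_overlap(registry),
      emt_class_counts = as.list(table(strata$emt_class)),
      mcam_class_counts = as.list(table(strata$mcam_class)),
      outputs = c("scores.tsv", "strata.tsv",
                  if (!is.null(subpops)) "subpops.tsv", "stats.json"))
    jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    summary
  }, emtstrat_error = function(e) {
    abort_emt(paste0("pipeline stage '", stage, "' failed: ",
                     conditionMessage(e)), class(e)[1])
  })
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
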