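#' Synthetic-data generator configuration
#'
#' Defaults emulate the statistical structure the stratification analysis
#' assumes in a breast-tumour single-cell atlas: malignant cells occupy a
#' latent EMT position t in [0,1] drawn from a three-component Beta mixture
#' with 78/18/4% mass (epithelial-like, hybrid, mesenchymal-like); normal
#' epithelium sits in the epithelial component; MCAM expression is sparse
#' (about 4% of malignant and 10% of normal-epithelial cells expressing, by
#' calibrated Bernoulli gates) with expressed levels rising along t; the
#' endothelial and perivascular compartments express MCAM (and KDR / CSPG4
#' respectively) at a high vascular mean; bulk samples are cell-type mixtures
#' whose MCAM and angiogenesis-gene values track the vascular fraction; and
#' promoter methylation M-values fall linearly with expression.
#'
#' @param seed integer seed; identical config + seed give byte-identical
#'   output.
#' @param n_cells named integer vector of cells per type.
#' @param emt_mixture_weights 3-vector of latent-class masses (sums to 1).
#' @param emt_component_shapes 3x2 matrix of Beta shape pairs for the latent
#'   classes (rows: low, med, high).
#' @param epithelial_amplitude,mesenchymal_amplitude expected log-expression
#'   of a marker gene in a fully epithelial (t = 0) / mesenchymal (t = 1)
#'   cell.
#' @param noise_sd per-gene-and-cell Gaussian noise on the log scale.
#' @param dropout_midpoint d0 of the dropout model: a value with underlying
#'   mean mu is zeroed with probability 1 - min(1, mu/d0).
#' @param mcam_gate_base named per-cell-type baseline of the MCAM expressing
#'   probability (calibrated so the default expressing fractions are 0.04
#'   malignant / 0.10 normal epithelial after the level draw).
#' @param mcam_gate_slope increase of expressing probability per unit t.
#' @param mcam_level_slope,mcam_level_intercept expressed MCAM level mean =
#'   slope * t + intercept.
#' @param vascular_mcam_mean MCAM/KDR/CSPG4 level in endothelial and
#'   perivascular cells (free parameter; the atlas reports only "high").
#' @param sig_amplitude peak expected level of invasion/stemness signature
#'   genes.
#' @param hybrid_peak if `TRUE`, invasion/stemness genes peak at
#'   `hybrid_peak_center` instead of rising monotonically with t, emulating
#'   maximal invasive/stem potential in nearly- but not fully-mesenchymal
#'   cells.
#' @param hybrid_peak_center,hybrid_peak_width Gaussian peak parameters on t.
#' @param n_decoy_genes number of pure-noise genes appended to the panel.
#' @param n_bulk number of bulk samples for [simulate_bulk()].
#' @param vascular_fraction_shapes Beta shape pair for the per-sample
#'   vascular fraction v.
#' @param bulk_scale linear scale factor of bulk values (so default bulk sEMT
#'   spans thousands, matching bulk-scale thresholds).
#' @param bulk_noise_sd lognormal (multiplicative) noise sd on bulk values.
#' @param bulk_noise_floor sd of the half-normal additive background on bulk
#'   values.
#' @param meth_intercept,meth_slope methylation coupling: probe M-values are
#'   drawn around `meth_intercept - meth_slope * expression`.
#' @param meth_probe_sd per-probe Gaussian sd of M-values.
#' @param n_probes probes per sample across the CpG island (default 9).
#' @param n_meth named vector: methylation samples per group.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1L,
    n_cells = c(malignant = 20000L, normal_epithelial = 3000L,
                endothelial = 1000L, perivascular = 500L,
                CAF = 1000L, immune = 4000L),
    emt_mixture_weights = c(0.78, 0.18, 0.04),
    emt_component_shapes = rbind(c(1.5, 10), c(6, 6), c(12, 2)),
    epithelial_amplitude = 2.0,
    mesenchymal_amplitude = 2.0,
    noise_sd = 0.4,
    dropout_midpoint = 2.5,
    mcam_gate_base = c(malignant = 0.0075768, normal_epithelial = 0.0914644),
    mcam_gate_slope = 0.15,
    mcam_level_slope = 3.0,
    mcam_level_intercept = 0.2,
    vascular_mcam_mean = 3.5,
    sig_amplitude = 2.0,
    hybrid_peak = FALSE,
    hybrid_peak_center = 0.75,
    hybrid_peak_width = 0.15,
    n_decoy_genes = 200L,
    n_bulk = 500L,
    vascular_fraction_shapes = c(2, 8),
    bulk_scale = 1000,
    bulk_noise_sd = 0.15,
    bulk_noise_floor = 25,
    meth_intercept = 2.0,
    meth_slope = 1.5,
    meth_probe_sd = 0.3,
    n_probes = 9L,
    n_meth = c(tumour = 150L, normal = 50L)) {
  cfg <- as.list(environment())
  if (abs(sum(emt_mixture_weights) - 1) > 1e-8 || any(emt_mixture_weights < 0))
    config_error("emt_mixture_weights must be non-negative and sum to 1")
  if (length(emt_mixture_weights) != 3 || nrow(emt_component_shapes) != 3)
    config_error("the latent EMT mixture has exactly three components")
  if (any(n_cells < 0) || any(n_meth < 0) || n_bulk < 0)
    config_error("counts must be non-negative")
  if (any(c(epithelial_amplitude, mesenchymal_amplitude, noise_sd,
            dropout_midpoint, meth_probe_sd, bulk_noise_sd) < 0))
    config_error("amplitudes and standard deviations must be non-negative")
  if (!all(c("malignant", "normal_epithelial") %in% names(mcam_gate_base)))
    config_error("mcam_gate_base needs malignant and normal_epithelial entries")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "synthetic_config")
}

# Panel of genes emitted by the generator. The invasion/stemness/angiogenesis
# members are synthetic stand-ins (the study-specific lists are supplemental
# and user-supplied); MMP1 deliberately appears in both the sEMT mesenchymal
# set and the stemness signature.
synthetic_gene_panel <- function(config) {
  c(EMT_EPITHELIAL_GENES, EMT_MESENCHYMAL_GENES,
    "MCAM", "KDR", "CSPG4", "EPCAM",
    "OVOL2", "TWIST1", "ESRP1", "QKI", "S100A4",
    sprintf("INVS%02d", 1:10), sprintf("CSCS%02d", 1:19),
    sprintf("ANGS%02d", 1:8),
    if (config$n_decoy_genes > 0) sprintf("DECOY%03d", seq_len(config$n_decoy_genes)))
}

# Truncated-Gaussian-plus-dropout expression draw on the log scale:
# x = max(0, mu + N(0, sd)), kept with probability min(1, mu / d0).
sim_value <- function(mu, sd, d0) {
  n <- length(mu)
  x <- pmax(0, mu + stats::rnorm(n, 0, sd))
  keep <- stats::runif(n) < pmin(1, mu / d0)
  x * keep
}

# Expected invasion/stemness signature-gene level as a function of latent t.
sig_mu <- function(t, config) {
  if (config$hybrid_peak) {
    config$sig_amplitude *
      exp(-(t - config$hybrid_peak_center)^2 / (2 * config$hybrid_peak_width^2))
  } else {
    config$sig_amplitude * t
  }
}

#' Simulate a single-cell expression matrix with ground truth
#'
#' Draws the cell types, latent EMT positions and per-gene log-normalised
#' expression values described in [synthetic_config()]. All randomness comes
#' from one stream seeded with `config$seed`, so identical configs reproduce
#' byte-identical outputs.
#'
#' @param config a [synthetic_config()].
#' @return list with `matrix` (log-normalised cell [expression_matrix()]),
#'   `annotation` (an [obs_annotation()]) and `truth` (data.frame: `obs_id`,
#'   `cell_type`, `latent_t`, `latent_class`; latents are `NA` outside the
#'   epithelial lineage).
#' @export
simulate_cells <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  types <- rep(names(config$n_cells), times = config$n_cells)
  n <- length(types)
  if (n == 0) config_error("no cells requested")
  ids <- sprintf("cell_%06d", seq_len(n))
  patients <- sample(sprintf("P%02d", 1:6), n, replace = TRUE)
  subtypes <- c(P01 = "TNBC", P02 = "ER+", P03 = "TNBC",
                P04 = "ER+", P05 = "HER2+", P06 = "ER+")[patients]

  # latent EMT position: malignant cells from the mixture, normal epithelium
  # pinned to the epithelial component, others undefined
  cls <- rep(NA_integer_, n)
  t <- rep(NA_real_, n)
  mal <- types == "malignant"
  nep <- types == "normal_epithelial"
  cls[mal] <- sample.int(3, sum(mal), replace = TRUE,
                         prob = config$emt_mixture_weights)
  cls[nep] <- 1L
  epi_lin <- mal | nep
  sh <- config$emt_component_shapes
  t[epi_lin] <- stats::rbeta(sum(epi_lin), sh[cls[epi_lin], 1], sh[cls[epi_lin], 2])

  genes <- synthetic_gene_panel(config)
  values <- matrix(0, nrow = n, ncol = length(genes),
                   dimnames = list(ids, genes))
  sd <- config$noise_sd; d0 <- config$dropout_midpoint
  draw <- function(mu) sim_value(mu, sd, d0)
  te <- t[epi_lin]

  for (g in EMT_EPITHELIAL_GENES)
    values[epi_lin, g] <- draw(config$epithelial_amplitude * (1 - te))
  for (g in EMT_MESENCHYMAL_GENES)
    values[epi_lin, g] <- draw(config$mesenchymal_amplitude * te)
  for (g in c("OVOL2", "ESRP1"))
    values[epi_lin, g] <- draw(2.0 * (1 - te))
  for (g in c("TWIST1", "QKI", "S100A4"))
    values[epi_lin, g] <- draw(2.0 * te)
  values[mal, "EPCAM"] <- draw(rep(2.5, sum(mal)))
  values[nep, "EPCAM"] <- draw(rep(1.5, sum(nep)))
  for (g in c(sprintf("INVS%02d", 1:10), sprintf("CSCS%02d", 1:19)))
    values[epi_lin, g] <- draw(sig_mu(te, config))

  # sparse MCAM in the epithelial lineage: Bernoulli gate rising with t,
  # expressed level c*t + intercept
  gate_base <- ifelse(mal[epi_lin],
                      config$mcam_gate_base[["malignant"]],
                      config$mcam_gate_base[["normal_epithelial"]])
  gate_p <- pmin(1, pmax(0, gate_base + config$mcam_gate_slope * te))
  gate <- stats::runif(sum(epi_lin)) < gate_p
  level <- pmax(0, config$mcam_level_slope * te + config$mcam_level_intercept +
                  stats::rnorm(sum(epi_lin), 0, sd))
  values[epi_lin, "MCAM"] <- ifelse(gate, level, 0)

  vasc <- config$vascular_mcam_mean
  endo <- types == "endothelial"; pvc <- types == "perivascular"
  if (any(endo)) {
    values[endo, "KDR"] <- draw(rep(vasc, sum(endo)))
    values[endo, "MCAM"] <- draw(rep(vasc, sum(endo)))
    for (g in sprintf("ANGS%02d", 1:8))
      values[endo, g] <- draw(rep(vasc, sum(endo)))
  }
  if (any(pvc)) {
    values[pvc, "CSPG4"] <- draw(rep(vasc, sum(pvc)))
    values[pvc, "MCAM"] <- draw(rep(vasc, sum(pvc)))
    for (g in sprintf("ANGS%02d", 1:8))
      values[pvc, g] <- draw(rep(vasc, sum(pvc)))
  }
  if (config$n_decoy_genes > 0)
    for (g in sprintf("DECOY%03d", seq_len(config$n_decoy_genes)))
      values[, g] <- sim_value(rep(1.0, n), sd, d0)

  mat <- expression_matrix(values, ids, genes,
                           scale = "log_normalized", obs_kind = "cell")
  ann <- obs_annotation(ids, patients, types, subtypes)
  truth <- data.frame(obs_id = ids, cell_type = types,
                      latent_t = t, latent_class = cls,
                      stringsAsFactors = FALSE)
  list(matrix = mat, annotation = ann, truth = truth)
}

# Expected (noise-free) per-compartment expression profile for one bulk
# sample with malignant latent position t. Rows: genes; the compartment
# weights mix these into the bulk value.
bulk_profiles <- function(genes, t, config) {
  p <- matrix(0, nrow = length(genes), ncol = 5,
              dimnames = list(genes, c("malignant", "normal_epithelial",
                                       "stroma", "endothelial", "perivascular")))
  t_norm <- 0.13  # population-mean latent position of normal epithelium
  p[EMT_EPITHELIAL_GENES, "malignant"] <- config$epithelial_amplitude * (1 - t)
  p[EMT_EPITHELIAL_GENES, "normal_epithelial"] <- config$epithelial_amplitude * (1 - t_norm)
  p[EMT_MESENCHYMAL_GENES, "malignant"] <- config$mesenchymal_amplitude * t
  p[EMT_MESENCHYMAL_GENES, "normal_epithelial"] <- config$mesenchymal_amplitude * t_norm
  p[EMT_MESENCHYMAL_GENES, "stroma"] <- 2.0  # CAF-like VIM/FN1 background
  p[c("OVOL2", "ESRP1"), "malignant"] <- 2 * (1 - t)
  p[c("TWIST1", "QKI", "S100A4"), "malignant"] <- 2 * t
  p["EPCAM", c("malignant", "normal_epithelial")] <- c(2.5, 1.5)
  sig <- c(sprintf("INVS%02d", 1:10), sprintf("CSCS%02d", 1:19))
  p[sig, "malignant"] <- sig_mu(t, config)
  ang <- sprintf("ANGS%02d", 1:8)
  p[ang, c("endothelial", "perivascular")] <- config$vascular_mcam_mean
  p["KDR", "endothelial"] <- config$vascular_mcam_mean
  p["CSPG4", "perivascular"] <- config$vascular_mcam_mean
  p["MCAM", c("endothelial", "perivascular")] <- config$vascular_mcam_mean
  p["MCAM", "malignant"] <- 0.35 * t  # mesenchymal malignant contribution
  dec <- grep("^DECOY", genes, value = TRUE)
  if (length(dec)) p[dec, ] <- 1.0
  p
}

#' Simulate bulk tumour samples as cell-type mixtures
#'
#' Each sample draws a vascular fraction v (split 60/40 between endothelial
#' and perivascular compartments) and a malignant latent EMT position from
#' the same mixture as the cells; the remaining mass is split 55/15/30 across
#' malignant, normal-epithelial and stromal compartments. Per-gene bulk
#' values are the weighted compartment profiles on a linear scale
#' (`bulk_scale`), with multiplicative lognormal noise and a half-normal
#' background floor. Angiogenesis genes and MCAM therefore track v, and MCAM
#' additionally tracks the mesenchymal malignant fraction.
#'
#' @param config a [synthetic_config()].
#' @return list with `matrix` (linear-scale bulk [expression_matrix()]) and
#'   `truth` (data.frame: `sample_id`, `vascular_fraction`,
#'   `mean_malignant_t`).
#' @export
simulate_bulk <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  nb <- config$n_bulk
  if (nb == 0) config_error("no bulk samples requested")
  ids <- sprintf("sample_%04d", seq_len(nb))
  v <- stats::rbeta(nb, config$vascular_fraction_shapes[1],
                    config$vascular_fraction_shapes[2])
  cls <- sample.int(3, nb, replace = TRUE, prob = config$emt_mixture_weights)
  sh <- config$emt_component_shapes
  t <- stats::rbeta(nb, sh[cls, 1], sh[cls, 2])

  genes <- synthetic_gene_panel(config)
  values <- matrix(0, nrow = nb, ncol = length(genes),
                   dimnames = list(ids, genes))
  for (i in seq_len(nb)) {
    w <- c(malignant = 0.55 * (1 - v[i]),
           normal_epithelial = 0.15 * (1 - v[i]),
           stroma = 0.30 * (1 - v[i]),
           endothelial = 0.6 * v[i],
           perivascular = 0.4 * v[i])
    prof <- bulk_profiles(genes, t[i], config)
    mu <- config$bulk_scale * as.numeric(prof %*% w)
    values[i, ] <- mu * exp(stats::rnorm(length(mu), 0, config$bulk_noise_sd)) +
      abs(stats::rnorm(length(mu), 0, config$bulk_noise_floor))
  }
  mat <- expression_matrix(values, ids, genes,
                           scale = "linear", obs_kind = "bulk_sample")
  truth <- data.frame(sample_id = ids, vascular_fraction = v,
                      mean_malignant_t = t, stringsAsFactors = FALSE)
  list(matrix = mat, truth = truth)
}

#' Simulate promoter methylation M-values coupled to expression
#'
#' Draws `n_probes` M-values per sample around
#' `meth_intercept - meth_slope * expression`. When no expression vector is
#' supplied, per-sample expression is drawn with the tumour group lower than
#' the normal group (so tumours are more methylated on average, the inverse
#' coupling seen at a silenced promoter).
#'
#' @param config a [synthetic_config()].
#' @param expression optional numeric vector of per-sample expression values
#'   named by sample id (must accompany `groups`).
#' @param groups optional character vector (`"tumour"`/`"normal"`) parallel
#'   to `expression`.
#' @return list with `table` (a [methylation_table()]) and `expression`
#'   (named vector actually used).
#' @export
simulate_methylation <- function(config = synthetic_config(),
                                 expression = NULL, groups = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  if (is.null(expression)) {
    nt <- config$n_meth[["tumour"]]; nn <- config$n_meth[["normal"]]
    expression <- c(pmax(0, stats::rnorm(nt, 1.0, 0.5)),
                    pmax(0, stats::rnorm(nn, 2.5, 0.5)))
    groups <- rep(c("tumour", "normal"), c(nt, nn))
    names(expression) <- sprintf("meth_%04d", seq_along(expression))
  } else {
    if (is.null(groups) || length(groups) != length(expression))
      input_error("groups must accompany expression, one label per sample")
    if (is.null(names(expression)))
      names(expression) <- sprintf("meth_%04d", seq_along(expression))
  }
  ns <- length(expression)
  mu <- config$meth_intercept - config$meth_slope * expression
  M <- matrix(stats::rnorm(ns * config$n_probes, rep(mu, config$n_probes),
                           config$meth_probe_sd),
              nrow = ns, ncol = config$n_probes,
              dimnames = list(names(expression),
                              sprintf("probe%02d", seq_len(config$n_probes))))
  list(table = methylation_table(M, names(expression), groups),
       expression = expression)
}
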