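# Fixture builders and independent brute-force oracles shared across tests.

make_matrix <- function(values, obs_ids = NULL, gene_ids = NULL,
                        scale = "log_normalized", obs_kind = "cell") {
  values <- as.matrix(values)
  if (is.null(obs_ids)) obs_ids <- sprintf("obs%02d", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- sprintf("G%03d", seq_len(ncol(values)))
  expression_matrix(values, obs_ids, gene_ids, scale = scale, obs_kind = obs_kind)
}

# random non-negative matrix whose columns include the 12 built-in EMT genes
random_emt_matrix <- function(n_obs, n_extra = 0, seed = 1) {
  set.seed(seed)
  genes <- c("CDH1", "GRHL2", "ITGB4", "KRT5", "KRT8", "FST",
             "CDH2", "ZEB1", "VIM", "MMP1", "FN1", "TGFB1I1")
  if (n_extra > 0) genes <- c(genes, sprintf("EXTRA%03d", seq_len(n_extra)))
  v <- matrix(round(runif(n_obs * length(genes), 0, 5), 3),
              nrow = n_obs, dimnames = NULL)
  make_matrix(v, gene_ids = genes)
}

# --- independent oracles ----------------------------------------------------

# per-observation loop over explicit gene sets (never touches score_signature)
oracle_scores <- function(matrix, positive, negative = character(),
                          aggregation = "sum_difference") {
  v <- as.matrix(matrix$values)
  sapply(seq_len(nrow(v)), function(i) {
    if (aggregation == "sum_difference") {
      s <- 0
      for (g in positive) s <- s + v[i, g]
      for (g in negative) s <- s - v[i, g]
      s
    } else {
      mean(sapply(positive, function(g) v[i, g]))
    }
  })
}

# Mann-Whitney U (pairwise count definition) and its exact two-tailed p by
# full enumeration of group assignments of the pooled sample.
oracle_mw_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_obs <- oracle_mw_u(x, y)
  sets <- utils::combn(length(pooled), n1)
  us <- apply(sets, 2, function(idx)
    oracle_mw_u(pooled[idx], pooled[-idx]))
  eps <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + eps), mean(us >= u_obs - eps)))
}

# Wilcoxon signed-rank exact two-tailed p by full 2^n sign enumeration,
# using its own midrank computation.
oracle_wsr_p <- function(x, y) {
  d <- (x - y)[x != y]
  a <- abs(d)
  r <- sapply(a, function(ai) sum(a < ai) + (sum(a == ai) + 1) / 2)
  wplus_obs <- sum(r[d > 0])
  n <- length(d)
  ws <- sapply(0:(2^n - 1), function(mask) {
    bits <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(r[bits])
  })
  eps <- 1e-9
  min(1, 2 * min(mean(ws <= wplus_obs + eps), mean(ws >= wplus_obs - eps)))
}

# tiny synthetic config for fast structural tests; overrides win
small_config <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(seed = seed,
         n_cells = c(malignant = 2000L, normal_epithelial = 500L,
                     endothelial = 100L, perivascular = 50L,
                     CAF = 100L, immune = 200L),
         n_decoy_genes = 20L,
         n_bulk = 200L),
    list(...))
  do.call(synthetic_config, args)
}
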