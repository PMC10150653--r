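# emtstrat

Gene-signature scoring and EMT-spectrum stratification of breast-cancer
expression data.

## The problem

Malignant epithelial cells do not simply switch between epithelial and
mesenchymal states during epithelial-to-mesenchymal transition (EMT): they
occupy a continuum, and intermediate hybrid E/M states are the ones most
strongly linked to invasion and metastasis. The adhesion receptor gene MCAM
(CD146) is expressed heterogeneously across that continuum — sparsely in
malignant cells, strongly in tumour vasculature — which confounds bulk
expression and survival analyses. `emtstrat` is for computational biologists
who want to reproduce or extend this kind of stratified single-cell /
bulk analysis with auditable, deterministic code.

## What it computes

* **sEMT**, a sum-difference score per observation:
  `sum(CDH2, ZEB1, VIM, MMP1, FN1, TGFB1I1) − sum(CDH1, GRHL2, ITGB4, KRT5, KRT8, FST)`
  (mesenchymal minus epithelial marker expression; higher = more
  mesenchymal), plus mean-expression **sInv**, **sCSC** and **sAng**
  signatures loaded from a user-supplied gene-list file.
* **EMT classes** low / med / high by half-open thresholds — defaults 0 and 5
  for log-normalised cells, 2000 and 5000 for linear bulk values — or
  boundaries calibrated from the score distribution (78th/96th percentiles).
* **MCAM tri-partition** within each class: non-expressers are MCAM-neg; the
  expressers are ranked and split into equal MCAM-low / MCAM-high halves
  (odd cell to low).
* The **nine-subpopulation summary** (EMT class × MCAM class) with mean
  sInv/sCSC per cell and their Spearman correlation.
* **Nonparametric statistics** with recorded exact/approximate methods:
  two-tailed Mann-Whitney U, Wilcoxon matched-pairs signed-rank, Spearman
  with Fisher-z confidence intervals; expressing-cell proportions; promoter
  methylation M-value summaries against matched expression.
* A seeded **synthetic-data generator** (single cells, bulk mixtures,
  methylation tables) with latent ground truth, used to validate every stage.

Readers for MatrixMarket triplet and dense TSV matrices are included; the
measurement scale (`log_normalized` / `linear`) is always declared, never
inferred, so cell thresholds cannot be applied to bulk data by accident.

## Worked example

```r
library(emtstrat)

cfg <- synthetic_config(seed = 1,
                        n_cells = c(malignant = 5000L, normal_epithelial = 1000L,
                                    endothelial = 300L, perivascular = 150L,
                                    CAF = 300L, immune = 600L))
sim <- simulate_cells(cfg)
sim$matrix
#> <expression_matrix> 7350 cells x 258 genes [log_normalized]

scores <- score_all(sim$matrix, synthetic_signature_registry())
mal <- sim$annotation$obs_id[sim$annotation$cell_type == "malignant"]
sub <- scores[scores$obs_id %in% mal, ]

thr <- calibrate_thresholds(sub$sEMT)   # population-calibrated boundaries
strata <- build_strata(sub, sim$matrix, thr)
tab <- cross_tabulate(strata, sub)
tab
#>   emt_class mcam_class    n mean_sInv mean_sCSC
#> 1       low        neg 3788     0.047     0.047
#> 2       med        neg  837     0.400     0.406
#> 3      high        neg  175     1.105     1.124
#> 4       low        low   56     0.048     0.043
#> 5       med        low   32     0.408     0.358
#> 6      high        low   13     0.858     0.950
#> 7       low       high   56     0.147     0.130
#> 8       med       high   31     0.724     0.681
#> 9      high       high   12     1.374     1.251

subpopulation_correlation(tab)
#> Spearman r = 0.9667 [0.8451, 0.9932], p = 2.15503e-05 (n = 9)

proportion_expressing(sim$matrix, "MCAM", mal)$fraction
#> [1] 0.04
```

The nine rows are the EMT-by-MCAM subpopulations: invasion and stemness
means rise along the EMT spectrum, the two means are strongly rank-
correlated across subpopulations, and 4% of malignant cells express MCAM —
the sparse, EMT-coupled expression structure the stratification is designed
to expose. In `hybrid_peak` simulation mode the EMT-high/MCAM-low cell of
the table carries the maximum combined sInv + sCSC.

`run_pipeline()` executes the whole chain (simulate or read → score →
stratify → report) from a config list or YAML file, writing `scores.tsv`,
`strata.tsv`, `subpops.tsv`, `stats.json` and a `run_summary.json` that
records the seed, thresholds and exact gene lists used. A thin command-line
wrapper lives at `inst/cli/emtstrat.R`.

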