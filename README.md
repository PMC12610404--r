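# dxgenes

Differentially explained genes (DXGs) for single-cell transcriptomics: find
the genes that drive a neural classifier's decisions, not just the genes
whose expression shifts.

## The problem

Classical differential expression (DEG) testing compares raw expression
between two groups of cells and, on sparse and noisy single-cell data, tends
to flood its hit lists with genes of marginal relevance. `dxgenes`
implements an alternative: train a classifier to recognize a cell's species,
cell type and disease state from its transcriptome, attribute each
prediction to individual genes with Shapley values, and statistically test
those *attribution scores* between cell groups. A gene is differentially
explained when the model relies on it differently in, say, cardiomyocytes
from failing versus healthy hearts — a direct, model-based notion of
disease relevance. The package is aimed at computational biologists working
with annotated single-cell/single-nucleus expression matrices who want
importance-based marker discovery alongside classical DEG lists.

## What is inside

* **Data layer** — readers/writers for Matrix-Market (10x-style) triplet
  directories and dense CSV/TSV, barcode QC (detected-gene bounds,
  mitochondrial fraction), counts-per-10k log-normalization, stratified
  train/validation splitting, and the 13-class one-hot label scheme
  (2 species + 7 cell types + 4 disease states).
* **Networks** — a denoising autoencoder (encoder 5000/2400/350, decoder
  2200/5150 by default) trained under L2 loss, and a multi-label MLP
  (795/230/105) with sigmoid outputs trained under a differentiable macro F1
  loss built from soft confusion counts:
  `pr = TP/(TP+FP)`, `rc = TP/(TP+FN)`, `F1_loss = 1 − mean_c 2·pr·rc/(pr+rc)`.
  Adam with the plateau schedule (lr 0.001, ×0.1 after 25 stagnant epochs,
  floor 1e-7, stop at 500 epochs or 50 stagnant); compiled (RcppArmadillo)
  and pure-R reference engines that produce identical histories.
* **Attribution** — permutation-sampling interventional Shapley values with
  antithetic pairs against a 1000-cell background, plus an exact `2^d`
  enumerator used as the oracle in the tests; mitochondrial exclusion and
  rowwise Z-standardization.
* **DXG statistics** — Welch t / Wilcoxon per gene on standardized
  attribution scores, Benjamini–Hochberg FDR, and the signed cube-root fold
  change `FC³ = cbrt(mean_A) − cbrt(mean_B)`; a Wilcoxon DEG comparator with
  the reference tool's default filters.
* **Enrichment benchmark** — per-gene ranking score
  `sign(FC)·log10(|FC/p_bin|+1)` (`p_bin = 0.1` iff p < 0.05), an in-repo
  preranked GSEA engine with seeded permutation p-values, keyword-derived
  truth sets, and the pathway-recovery F1.
* **Synthetic generator** — negative-binomial counts with planted,
  direction-signed marker programs across the full label grid, so every
  stage can be validated against a known ground truth.
* **Pipeline** — `run_dxg_study()` (in-memory) and `run_pipeline()`
  (staged, resumable, manifest-writing) plus a thin CLI at
  `inst/cli/dxgenes`.

## A worked example

The whole method on one seeded synthetic dataset (11,200 cells × 300 genes,
13 classes, HFpEF-vs-healthy contrast in human cardiomyocytes):

```r
library(dxgenes)

res <- run_dxg_study(study_config(seed = 1), verbose = TRUE)
#> validation macro F1 = 0.9135
res$evaluation$rates
#>   species cell_type   disease
#> 0.9919451 0.8918683 0.9210742
head(res$dxg[, c("gene", "mean_A", "mean_B", "fc3", "p_adj")], 3)
#>       gene    mean_A     mean_B      fc3        p_adj
#> 1 gene0093 0.4583371 -0.4491703 1.536851 8.623333e-09
#> 2 gene0255 0.4479270 -0.4389684 1.525127 1.133642e-08
#> 3 gene0195 0.4119402 -0.4037014 1.483138 3.409985e-07
str(res$recovery)
#> $ n_planted: int 15
#> $ n_sig    : int 19
#> $ recall   : num 1
#> $ precision: num 0.789
c(res$benchmark$dxg$f1, res$benchmark$deg$f1)
#> [1] 1 1
```

Reading the output: the classifier separates the three label categories at
rates in the regime the method was designed for; the DXG table's top genes
are planted HFpEF markers (`mean_A`/`mean_B` are group means of
standardized attribution scores of the held-out cells, `fc3` the signed
cube-root fold change); `recovery` scores the significant DXGs against the
planted truth (all 15 markers recovered, 4 extra calls); and the final
benchmark compares pathway recovery (enrichment F1 against the
keyword-derived truth set) for the attribution-based versus the
expression-based ranking — both recover the planted marker programs
perfectly here.

The staged equivalent from a shell:

```sh
Rscript inst/cli/dxgenes all --config my_study.yaml
```

where the YAML gives `out_dir`, `seed` and any overrides; each stage writes
its artifacts and a JSON manifest and is skipped on re-runs unless
`--force`.

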