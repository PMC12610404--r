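---
title: "Differential explanation analysis: models, choices, and caveats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential explanation analysis: models, choices, and caveats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dxgenes)
```

## The method in one paragraph

`dxgenes` identifies *differentially explained genes* (DXGs): genes whose
importance to a neural classifier's decision — measured by Shapley
attribution scores — differs between two groups of cells, rather than genes
whose raw expression differs. The pipeline is: (1) log-normalize single-cell
counts; (2) train a denoising autoencoder (DAE) on the expression profiles
under mean-squared-error (L2) loss; (3) train a multi-label perceptron (MLP)
on the denoised profiles to predict, through 13 sigmoid output nodes, a
cell's species (2), cell type (7) and disease state (4), minimizing a
differentiable macro F1 loss; (4) compute per-cell, per-gene interventional
Shapley values for a chosen output node against a background of 1000 random
training cells; (5) compare the Z-standardized scores of two cell groups per
gene with a two-sample test, Benjamini–Hochberg-adjusted, with a signed
cube-root fold change `FC3 = cbrt(mean_A) − cbrt(mean_B)` as the effect
size; (6) rank genes by `sign(FC)·log10(|FC/p_bin| + 1)` (`p_bin` = 0.1 when
p < 0.05, else 1) and run preranked gene set enrichment; (7) benchmark the
significant pathways against a keyword-derived truth set with an F1 score.

## The classifier stack

**Loss functions.** The DAE minimizes the mean over all cells and genes of
the squared reconstruction error. The MLP minimizes one minus the mean over
classes of a *soft* F1 score, built from probability-weighted confusion
counts `TP = Σ p·y`, `FP = Σ p·(1−y)`, `FN = Σ (1−p)·y`, with precision
`TP/(TP+FP)`, recall `TP/(TP+FN)` and their harmonic mean. The soft counts
make the loss differentiable; the analytic gradient
`∂F1_c/∂p_ic = 2(y_ic·D_c − TP_c)/D_c²` (with `D = 2TP+FP+FN`) is verified
against finite differences in the test suite. On hard 0/1 inputs the soft
loss equals one minus the classical hard-count macro F1 exactly. A class
whose soft `TP+FP` or `TP+FN` is zero contributes F1 = 0 (loss 1), with a
warning.

**Training schedule.** Both networks use Adam (learning rate 0.001) with a
plateau schedule: improvement means a *strictly* lower validation loss; after
25 epochs without improvement the learning rate is multiplied by 0.1 (floored
at 1e-7), and training stops after 500 epochs or 50 epochs without
improvement. The best-validation weights are restored at the end — with a
strict-improvement rule this is the natural reading of "monitoring", and it
makes early stopping harmless. Weight initialization is fan-in-scaled
Gaussian with an explicit seed; all batch shuffles come from R's RNG, so
training is bit-reproducible per seed (the compiled and pure-R engines are
asserted to produce identical histories).

**Cross-entropy warm-up.** The soft-count F1 loss has a failure mode worth
knowing about: early in training it rewards pushing every output toward 1
(all-positive prediction already scores `F1 = 2π/(1+π)` at prevalence π),
and once a node's sigmoid saturates to exactly 1.0 in floating point its
gradient `p(1−p)` is identically zero — the node is dead and no amount of
further training recovers it (symptom: a per-class F1 pinned at exactly
2/3). The classifier therefore runs a short binary cross-entropy warm-up
(`warmup_epochs`, default 10) before switching to the macro F1 objective:
the cross-entropy logit gradient `p − y` does not vanish at saturation, so
the warm-up parks the network in a healthy region first. A small decoupled
weight decay (default 1e-4) is also applied to the classifier's weights.
Both are the package's own robustness choices; the minimized objective
remains the macro F1 loss.

**Architecture defaults.** The production defaults (encoder 5000/2400/350,
decoder 2200/5150; MLP 795/230/105; batch 10240) are the tuned values for a
16,545-gene atlas. For the 300-gene synthetic study we use encoder 128/64,
decoder 128, MLP 64/32, batch 128 — layer widths scaled roughly with the
input dimension (an undersized autoencoder visibly collapses the
lowest-variance category structure, cell type, in its reconstructions),
batch size scaled so an epoch still takes tens of gradient steps. The DAE's
output layer is linear: ReLU belongs to the hidden layers, and a linear
output is the standard pairing with the squared-error objective (a ReLU
output can lock dead units at zero).
Hidden-layer activations are ReLU, the classification layer sigmoid, and
predicted labels are probabilities *strictly above* 0.5, so a probability of
exactly 0.5 maps to 0.

**Evaluation.** Thirteen per-node precision/recall/F1 values are computed
from hard thresholded labels; a class never predicted and never true reports
1.0 with a degeneracy flag so macro averages stay defined. Confusion matrices
per category use block-wise argmax (the thresholded multi-label output can
produce zero or two positives in a block); rows are truth, columns
predictions, and the per-category correct classification rate is the
unweighted mean over classes of the diagonal fraction.

## Shapley attribution

The production estimator is permutation-sampling interventional Shapley:
for each explained cell, random feature permutations are drawn, each paired
with one background cell, and the model is evaluated along the chain that
morphs the background into the explained cell one gene at a time; each
gene's marginal output change is accumulated. Antithetic pairs (each
permutation together with its reversal) cancel first-order position noise.
The estimator is unbiased for exact interventional Shapley values — the
package also ships `shapley_exact()`, a full `2^d` enumeration used as the
oracle in the test suite (linear-model closed form, efficiency,
symmetry, null-player and linearity axioms all hold to 1e-10 there).

Mitochondrial genes are excluded *after* attribution and *before* any
standardization, so their scores cannot influence row means or standard
deviations. The attribution target is the pre-threshold sigmoid probability
of one output node.

**Which model is explained.** Two options are exposed through
`class_model()`: explaining the MLP on DAE-reconstructed expression, or
explaining the DAE∘MLP composite on raw normalized expression. The package's
study pipeline uses the composite, for a reason that only becomes visible at
small panel sizes: a denoising autoencoder imputes every gene from its
latent state, so on a 300-gene panel the *reconstructed* value of a gene
that is unrelated to a disease still carries disease signal (in our
synthetic study two thirds of unrelated genes differ significantly between
groups in reconstructed space, and none do in normalized space).
Attribution on reconstructed inputs then correctly — but unhelpfully —
assigns disease relevance to unrelated genes. Explaining the composite keeps
the attribution in measured-gene coordinates.

## Standardization of attribution scores, and why it matters

`z_transform_rows()` implements per-cell (rowwise) standardization with the
population standard deviation: each cell's scores are centered on that
cell's mean score over genes and scaled by that cell's spread. `dxg_test()` however defaults to *per-gene* standardization across
the pooled cells (equivalent, for the test's inference, to testing raw
scores), with `standardization = "row"` available.

The reason is a small-panel artifact that follows directly from the
efficiency axiom. A cell's attributions sum to
`f(x) − mean_b f(b)`. For cells of the contrast class the sigmoid output
`f(x)` saturates near 1, for reference cells near 0, so the per-cell sum
differs by ~1 between groups. Rowwise centering subtracts the per-cell mean
— that difference divided by the number of genes — from *every* gene. With
G genes and a typical per-cell score spread σ, every null gene acquires a
spurious between-group shift of roughly `1/(G·σ)` standard units. At
G ≈ 16,000 this is negligible; at G = 300 it is ~0.3σ, which a t-test with
200 cells per group flags at arbitrarily small FDR: in our synthetic study
it pushes ~95% of unrelated genes below the significance threshold.
Per-gene standardization has no such coupling (each gene is standardized by
its own pooled moments, an affine map that leaves two-sample inference
untouched) and restores the intended behavior: planted disease markers are
recovered at high precision and recall. Both forms are first-class; the
rowwise transform remains available, contract-tested, and appropriate at
atlas scale.

## The DXG test

Groups are equality filters over (species, cell type, disease, sample).
`method = "auto"` runs a Shapiro–Wilk screen per gene (subsampled to 5000
values, the standard implementation limit) and picks Welch's t-test when the
median gene's p-value is consistent with normality, otherwise the Wilcoxon
rank-sum test; one decision is made for the whole comparison. The study
pipeline reports the screen but fixes `method = "t"` — a rank test would
additionally react to group differences in the scores' *shape* (the
saturated class has more dispersed attributions), which is not the question
the DXG test asks. The
"Student" test is implemented as Welch (unequal variances) —
attribution-score variances have no reason to be equal between groups. BH adjustment spans all
genes of one comparison. `FC3` uses signed cube roots
(`sign(x)·|x|^(1/3)`), which are defined for the negative, zero and positive
group means that standardized scores produce and compress skew much like a
log transform.

The expression-side comparator `deg_wilcoxon()` mirrors the reference
single-cell toolchain's defaults: natural-log fold change of group-mean
`expm1` expression with a +1 pseudocount, detection-fraction filter 0.1,
|logFC| filter 0.25, Wilcoxon rank-sum, BH. For enrichment ranking the
filters are disabled (the "nonfiltered" mode).

## Enrichment and the benchmark

The preranked engine is the standard weighted running-sum statistic (hits
advance by `|score|^w`, misses retreat uniformly; the enrichment score is
the maximum signed deviation; weight 1 by default). P-values come from
seeded gene-label permutations, two-sided on |ES|, BH-adjusted across sets.
The implementation is cross-checked in the tests against both a brute-force
running sum and an established library's statistic. Truth sets are built by
case-insensitive substring matching of keywords against term descriptions;
the benchmark F1 counts significant-and-matched terms as true positives,
significant-but-unmatched as false positives, and matched-but-missed as
false negatives (the only reading under which an F1 is computable).

## The synthetic generator

`generate_dataset()` emulates droplet-style data: negative-binomial counts
(dispersion 0.3) around `baseline_mean · gene_factor · cell_factor`
(log-normal gene and cell size factors, sd 0.3 and 0.2), Bernoulli dropout,
and planted marker genes on the full 2 species × 7 cell types × 4 disease
grid (13 classes; the first disease level is the unaffected reference and
has no markers). Markers are disjoint across labels; a quarter of each
label's markers are down-regulated. Cells carry a biological-sample label (2
samples per species × disease condition).

Defaults are calibrated so that the task's *attainable* separability mirrors
the study the generator stands in for: with 15 markers per label and 10%
dropout, a ridge-regression ceiling reaches ~99.6/97.6/93.8% per-category
accuracy, the same regime as the real study's reported 100/92.7/97.4%
classification rates. (An early parameterization with fewer markers and
heavier dropout capped *any* classifier near 85% — a synthetic task that
contradicts the phenomenon being modeled rather than emulating it.) What the
generator deliberately does **not** model: gene–gene correlation beyond
shared size factors, batch effects, ambient RNA, or cell-type abundance
imbalance. Passing tests on this generator therefore demonstrate the
pipeline's mechanics and statistical calibration, not robustness to those
real-data pathologies.

## Problem sizes used by the test suite

The shipped study configuration runs the complete pipeline per seed:
simulate the 13-class grid (11,200 cells × 300 genes), hold out one
biological sample per condition as the test set, split the remainder 80/20
stratified for training/validation, train DAE and MLP (≤150 epochs each),
attribute the held-out cells of the contrast groups (~100 per group) with 6
antithetic permutation pairs against a 1000-cell training background, run
the DXG test and the expression comparator on those same held-out cells,
enrich (2000 permutations, ~60 gene sets, permutation nulls pooled by set
size — the null depends only on set size, so sets of equal size share one
pool), and benchmark. One seed takes under two minutes on one CPU.

The holdout design matters beyond runtime. Attribution scores carry two
kinds of group differences: the planted biology, and small systematic
"leakage" effects on unrelated genes that any finitely-trained network
exhibits. Explaining *training* cells with very large groups gives the
two-sample test enough power to flag the leakage (precision collapses);
explaining held-out cells of one designated biological sample keeps the
test powered for real marker effects while leaving leakage below the FDR
threshold. The acceptance suite
runs ten seeds and takes medians; the type-I-error check uses 20 null
replicates of 500 cells × 300 genes with 2 permutation pairs and a fixed
random-weight network as the explained model (with no planted effect there
is nothing to learn, and the exchangeability argument behind the test's
calibration is conditional on any fixed model). Attribution noise from the
small permutation count only widens within-group variance; it does not bias
the test's size.

## Known limitations

* The networks are plain dense stacks; no convolutional, attention or
  dropout layers, and no hyperparameter search (layer sizes are inputs).
* Exact Shapley enumeration is limited to ≤15 features by construction;
  beyond that only the sampled estimator is available.
* The rowwise Z-transform / per-gene standardization choice materially
  changes results below ~1000 genes (see above); on targeted panels the
  per-gene default should be kept.
* `deg_wilcoxon` implements only the rank-sum comparator; hurdle-model and
  pseudobulk approaches are out of scope.
* The enrichment engine does no GO-graph propagation; terms are flat gene
  sets with name-table descriptions.
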