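---
title: "Methods: spatial single-cell analysis of IMC cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial single-cell analysis of IMC cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(imctme)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic validation does and does not show
about real data.

## Marker masks

Each antibody channel is reduced to a binary mask in five steps, with all
tunables held per marker in the panel (`mask_params()`), because mask
quality in practice is curated channel by channel.

1. **Median smoothing** (`median_window = 3`, pixels). A 3×3 median
   suppresses isolated hot pixels, a common artefact of metal-isotope
   counting, while preserving edges. Borders replicate the edge row/column.
2. **Intensity quantization** (`n_levels = 6`). Pixel intensities are
   clustered one-dimensionally into six levels. In one dimension the
   k-means optimum is a set of contiguous intervals of the sorted values,
   so instead of iterative k-means with restarts we compute the *global*
   optimum exactly by dynamic programming over the distinct values. This
   removes all initialisation dependence: identical inputs always produce
   identical levels, and the unit tests verify exact agreement with
   exhaustive enumeration of every possible interval partition.
   Continuous rasters are first histogrammed into at most 2,048 equal-width
   bins; the bin width is orders of magnitude below the noise scale of
   counts, and integer-valued rasters (the common IMC case after median
   smoothing) are solved without binning.
3. **Foreground selection** (`foreground_level`). Marker signal is bright
   on a dark background, so foreground is counted from the brightest level
   down: keeping `f` levels means level ≥ `max_level − f + 1`. The default
   (`NULL`) curates `f` per channel by the **largest-gap rule**: the
   ordered level means separate into a background run and a signal run,
   and the cut is placed above the largest jump between consecutive means.
   On the default signal model (20:1 on/off contrast) this reproduces what
   a human curator would pick; an explicit integer per marker overrides it.
4. **Blob removal** (`min_blob_area = 4` px). 8-connected components
   smaller than the threshold are removed. The operation is idempotent.
5. **Adaptive refinement** (optional, `adaptive_sensitivity = 0.4`,
   15×15 window). A locally adaptive mask — threshold
   `mean₁₅ₓ₁₅ · (1 − s·(1 − I/max I))`, so locally bright pixels get a
   proportionally lowered threshold — is **intersected** with the step-4
   mask. Whether the amalgamation of the refinement mask should be an
   intersection or a union is genuinely open; we chose intersection so
   that refinement can only remove pixels, which gives the useful
   invariant `refined ⊆ input` (property-tested) and cannot re-introduce
   noise that earlier steps removed.

Degenerate inputs: a constant channel quantizes to a single level and
yields an all-background mask (a single level carries no contrast); rasters
with fewer distinct values than levels collapse with a warning.

## Phenotyping

For each segmented cell, the majority vector counts, per lineage marker,
how many of the cell's pixels fall in that marker's mask. The argmax
assigns the type. Three conventions matter:

* **Ties** resolve by the panel's rank priority (lower rank wins), placing
  the most specific immune markers first, so that e.g. a FOXP3/CD4 tie is
  called a regulatory T cell.
* **All-zero vectors** become `"undefined"` rather than being forced into
  a type; fabricating calls would bias downstream composition.
* **Combination rules** (e.g. CD68 macrophages split by CD163, CD14
  monocytes split by CD16) take the secondary type when the secondary mask
  covers at least half the cell's pixels. The shipped 17-type panel preset
  (`luad_panel()`) is a documented default, not an assertion of any
  specific study's unpublished hierarchy.

Expression is summarized as the **raw** per-channel mean over the cell's
pixels (no transformation); the 95th-percentile normalization plus
z-scoring (`percentile_normalize()`, quantile type 7) is used only for
display matrices. Functional positivity uses a 0.5 foreground-pixel
fraction by default — no per-cell rule is standard, so the threshold is a
configurable parameter.

## Pairwise interaction testing

Cells interact when their masks come within `d = 6` px (inclusive). The
"within six pixels" convention could be read as boundary or centroid
distance; boundary distance is the biologically meaningful reading (two
large touching cells interact regardless of centroid distance), so it is
the default, with the centroid rule available. The statistic for an
ordered pair (A, B) is the mean B-neighbour count per A cell — the
convention of the permutation framework this test family descends from —
and the null shuffles all labels jointly within a core, keeping positions
and the adjacency graph fixed. P-values use the add-one estimator, so
`p ≥ 1/(n_perm + 1)` and a pair is called at α = 0.01 by the smaller of
the interaction/avoidance p-values. Note each direction is separately
calibrated at α (verified by simulation); the union call rate under the
null is therefore about 2α by construction. Group-level heatmaps average
signed calls (+1/−1/0) over the cores where the pair was testable;
fraction-significant is an obvious configurable alternative.

## Cellular neighbourhoods

Windows are the type-frequency vectors of each cell's `n = 10` nearest
neighbours (Euclidean distance on centroids, ties broken by cell id,
within cores only — cores are separate tissue). The index cell is
**excluded** from its own window by default; the literature contains both
conventions, so `include_self` is a flag. Windows from all cores are
clustered jointly (neighbourhoods are cohort-level objects) by mini-batch
k-means — k-means++ seeding, per-centre learning rates `1/count`, seeded
batches, final full assignment — implemented in-package and deterministic
given its seed. Batch size defaults to 100. Prevalence per core is
normalized to 100 % (largest-remainder rounding for display; raw fractions
are kept for statistics). The window-size sweep (`cn_sweep()`) refits over
`n = 3..30` at fixed `tCN` and reports every neighbourhood's survival
association, to show robustness of a finding to the windowing choice.

## Survival association

Any per-patient quantity is standardized over the analysis cohort and
split at z = 0 (z ≥ 0 is "high", inclusive). Patients with two cores
contribute the mean of their cores. Kaplan–Meier estimation and the
log-rank (Mantel–Cox) test with the standard discrete-ties formula are
delegated to the `survival` package behind the module interface, and the
wrappers are verified against hand-computed product-limit and O/E/V
oracles in the tests. Raw p-values are reported by default when scanning
many neighbourhoods, with an optional Benjamini–Hochberg column — the
scan mirrors exploratory practice, and adjusted values are one switch
away.

## Outcome prediction

The framework embeds each selected channel (scaled by its 99th percentile
into [0, 1]) with a pluggable backbone, concatenates the per-channel
embeddings in panel order, reduces them to 9 sparse principal components,
and classifies with an RBF-SVM (cost 1, bandwidth `1/(d·var)`) after
random oversampling of the training classes to parity. Folds are
stratified by class and grouped by patient — with two-core patients, any
other choice leaks a patient's second core into training.

Design choices worth recording:

* **Backbone registry.** The reference design uses an ImageNet-pretrained
  ResNet-50 whose penultimate layer yields 2,048 features per channel;
  any such model can be registered as a function `image → vector`. The
  built-in `testhash` backbone is a deterministic, download-free
  image-statistics embedding: translation-invariant multi-scale pooled
  moments (distribution summaries of block means at grids 2–32, global
  quantiles, foreground fractions, gradient statistics) pushed through a
  fixed random projection to 2,048 dimensions. Pooling mirrors the global
  average pooling of convolutional backbones: cores differing only in
  where cells landed embed nearby, cores differing in how clustered the
  signal is separate. All tests and validation run on `testhash`.
* **Sparse PCA.** "Mini-batch sparse PCA" names an algorithm family, not
  parameters. We implement sequential rank-one sparse PCA by truncated
  power iteration: each component keeps the `keep_x` largest-magnitude
  loadings (default: half the features), initialised from the exact
  leading singular vector and deflated in score space so components do
  not repeat. The fit is deterministic, reduces to exact PCA in the dense
  limit (verified against `prcomp`), is fitted on training folds only and
  applied to held-out cores by projection. Full-batch fitting is exact at
  desk-scale cohort sizes, which is why no stochastic mini-batching is
  needed.
* **Leakage canary.** Reduction and oversampling are fitted on training
  folds only; the tests permute held-out labels at fixed folds and assert
  the training-fold artifacts (centre, loadings, oversampling draw) are
  byte-identical.
* **Baseline.** The modal-class fraction; a 90/30 split scores exactly
  0.75.

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
validated:

* **Geometry.** 256×256 px cores at 1 µm/px stand in for ~1 mm² cores;
  density 90 cells per 10⁴ px² (~590 cells/core) keeps the packed area
  fraction realistic (~26 %). Cells are discs of radius 3 px — the
  simplest shape with enough pixels (~29) to make majority voting
  nontrivial — placed by a **hard-core** process (minimum centre spacing
  `2r − 1`, bounded retries) because cells have bodies; residual overlaps
  are truncated in placement order. Pure uniform placement was rejected
  after it produced sliver cells of 2–3 boundary pixels that no pixel
  vote could type — an artefact of overlapping discs, not of the method.
* **Types and signal.** Eight default types with an LUAD-like mixture
  (40 % tumour, 10 % endothelial, 50 % immune across six populations).
  Lineage channels read 10 counts on-target and 0.5 off-target (5 %
  off-target signal) under multiplicative log-normal noise (σ = 0.3 on
  the log scale) — IMC intensities are positive and right-skewed.
  Functional markers (Ki-67 in endothelium, HIF1α in neutrophils, pERK in
  helper T cells) mark planted positive subsets.
* **Spatial structure.** Niches cluster member types around shared
  centres (Gaussian spread `radius/2`); distinct niches repel each other
  (centres keep the summed radii apart) the way distinct tissue
  compartments do. Pairwise attraction moves each B cell a fraction
  `strength` of the way to its nearest A (stopping at contact);
  repulsion pushes B cells out of a 25 px radius. Both are bounded,
  monotone-in-strength displacements that the permutation test must
  detect; 0.5 is the conventional planting strength in the validation
  suite.
* **Outcomes.** Progression is logistic in realized per-core features
  (frequencies, niche prevalences and weights, mixing scores); survival
  is exponential proportional hazards (baseline mean 60 months) with
  independent exponential censoring calibrated to the requested fraction
  at baseline. The realized features used for sampling are returned as a
  sidecar, so every planted effect is auditable ground truth.

**What passing these checks shows — and does not.** The synthetic cohort
exercises the full statistical machinery on data with known answers:
mask/vote phenotyping fidelity, permutation-test calibration and power,
neighbourhood recovery (ARI ≥ 0.8 at planted conditions), survival power
(≥ 90 % at hazard ratio 2, n = 200, 20 % censoring) and the
spatial-beats-composition prediction ordering. It does **not** emulate
IMC spillover or isotope interference, segmentation errors (ground-truth
masks stand in for the external segmentation model), staining batch
effects, irregular cell shapes, or the marker-correlation structure of
real panels — so passing here validates the implementation, not any
claim about a particular tissue.

## Problem sizes and runtime choices

The validation suite runs at sizes chosen to exercise each property while
staying desk-scale: single cores of ~590 cells for phenotyping fidelity,
100-raster oracle sweeps at ≤ 64×64 px, 30 cores × 1,000 permutations for
calibration, 50 cores for planted-interaction recovery, six-core cohorts
for neighbourhood ARI, 200/500 replicate cohorts for survival power and
null uniformity, and a 120-core cohort for the prediction framework. The
numbered `analysis/` scripts use an 80-patient discovery-style cohort.

## Known limitations

* The real-data TIFF reader supports multipage stacks (page order = panel
  order) and per-marker directories; deposited datasets with other
  layouts need a thin adapter.
* The largest-gap foreground curation assumes bright-on-dark unimodal
  signal above background; channels with genuinely multimodal signal
  should set `foreground_level` explicitly.
* Exponential baseline hazards make survival times memoryless; planted
  effects are proportional by construction.
* The `testhash` backbone is translation invariant by design and cannot
  see chirality or absolute position; a learned convolutional backbone
  plugged into the registry may capture texture the pooled moments miss.
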