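---
title: "Reference-free evaluation of cell segmentation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free evaluation of cell segmentation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segqc)
```

## The evaluation problem

Given a multichannel fluorescence image of tissue and an indexed (label)
mask of cells — optionally with a matching nuclear mask — `segqc` asks:
*how plausible is this segmentation, judged only against the image
itself?* The approach rests on a small set of biological assumptions:

* tissue foreground should be covered by cells, and slide background
  should not be;
* every cell should contain exactly one nucleus, nested inside it;
* a tissue contains a limited number of cell types, and cells of one type
  should have similar channel composition, both in their nuclei and in
  their cytoplasmic/membrane compartment;
* leftover foreground that no cell claims should look like structureless
  background, not like missed cells;
* cell sizes within a tissue should not be wildly dispersed.

Each assumption is quantified by one or more of 14 metrics, and the
metrics are combined into one score by a principal-component model. None
of this requires a reference segmentation; a second segmentation can
nevertheless be compared directly with the symmetric benchmark functions.

## Mask processing

Methods that segment cells and nuclei independently produce orphan cells,
orphan nuclei, and nuclei that protrude through their cell boundary.
`match_cells_to_nuclei()` treats any cell/nucleus pair sharing at least
one pixel as a candidate, scores it by the *mismatch fraction* (nucleus
pixels outside the cell, as a fraction of the nucleus), and resolves
candidates greedily in ascending mismatch order while enforcing a
one-to-one pairing. Ties are broken by larger overlap, then smaller ids,
so results are deterministic. A nucleus overlapping two cells competes
for both and is assigned to at most one; whether it should remain
available to the second cell after losing the first is not obvious — the
global greedy resolution adopted here simply keeps the overall pairing
with the smallest mismatches.

`apply_repair()` then enforces the one-to-one contract in one of two
modes. `repair` trims each paired nucleus to its cell's extent; `strict`
discards every pair with a positive mismatch fraction. Both erase all
unmatched objects and relabel ids consecutively (the old-to-new map is
kept for traceability). The cell-excluding-nucleus (CEN) mask is the
per-id set difference of cell and nucleus. Cells whose nucleus fills
them completely have an empty CEN region; such ids are *retained* — they
still count as cells, and removing them would silently change the cell
count metric — but they are flagged and simply contribute nothing to CEN
statistics.

The match-quality metric FMCN is computed on the masks *before*
processing, as the Dice-style fraction `2·pairs / (cells + nuclei)`. This
penalises orphan cells and orphan nuclei symmetrically, is 1 exactly for
a perfect one-to-one segmentation, and is invariant to which mask is
called "cells".

## Foreground estimation

Several metrics need a tissue-foreground mask. The rule used here:
normalise each channel by its mean (so bright channels do not dominate),
average the normalised channels, apply an Otsu threshold, then a
morphological closing with a disc of radius 1 and hole filling. Constant
images yield an all-background mask. This is deliberately the simplest
defensible rule; it is isolated behind `compute_foreground()` so an
alternative is a one-line swap. On the synthetic fixtures it recovers
more than 99% of true cell pixels.

## The metric panel

With pixel size `p` (µm), image area `A = H·W·p²`, foreground `F`, and
cell pixels `C`:

* `NC = 100 · n_cells / A` — cells per 100 µm², computed on the matched
  (post-repair) cell mask.
* `FFC = |C ∩ F| / |F|`, `FBC = |C ∩ ¬F| / |¬F|` (reported as `1−FBC`),
  `FCF = |C ∩ F| / |C|`.
* `1/(ACVF+1)` and `FPCF` — over foreground pixels *outside* all cells,
  the mean per-channel coefficient of variation and the fraction of
  variance carried by the first principal component of the
  pixel-by-channel matrix. If cells cover the whole foreground, there are
  no such pixels and both metrics take their best value 1 — perfect
  coverage is the monotone best case, not an error.
* `1/(ACVC+1)`, `FPCC`, `AS` — cell-level homogeneity. Per-cell mean
  intensities are computed per channel over a compartment (nuclear and
  CEN separately in the full panel; the whole cell in the reduced panel),
  standardised by the per-channel mean, and partitioned by k-means for
  every k in 1..10 (k = 1 is the single trivial cluster; 10 random
  restarts under a fixed seed). For each k, the size-weighted mean of the
  per-cluster channel CV gives ACVC(k) and of the per-cluster PC1
  variance fraction gives FPCC(k); ACVC and FPCC are the means over k.
  AS is the mean silhouette width over k = 2..10. Weights sum to one for
  every k by construction.
* `1/(ln(CSSD)+1)` — CSSD is the population standard deviation of cell
  areas in µm² (resolution-independent), clamped to at least 1 before the
  logarithm so the transform is defined; uniform sizes map to 1.

All transformed metrics live in (0, 1]; AS in [−1, 1]. The reduced
10-metric panel (for segmentations without nuclear masks) drops FMCN and
computes the three cell-level metrics once, on whole cells.

Degenerate inputs follow explicit conventions rather than erroring:
fewer than 2 cells gives ACVC = 0 and FPCC = 1; fewer than 3 gives
AS = 0; identical feature rows give AS = 0 (zero distances carry no
cluster structure); clusters of size 1 are variance-free (CV 0, PC1
fraction 1); channels with zero mean contribute CV 0. Each is flagged
with a message when triggered.

### Why these clustering choices

The number of clusters is swept rather than estimated because the metric
should not depend on getting the type count right; averaging over k
rewards segmentations that look homogeneous at *every* granularity.
Features are divided by their per-channel mean (not z-scored) before
clustering: channel means are strictly positive physical intensities and
mean-scaling preserves each channel's relative dispersion, which is the
signal CV-based metrics build on. k-means itself is run with fixed seed
and 10 restarts so metric vectors are reproducible; when k reaches the
number of distinct feature rows the optimal partition (one cluster per
distinct row) is used directly, since k-means rejects that boundary case.

## The quality model

Metric rows are z-scored column-wise (zero-variance columns keep scale 1
so vector length is stable) and decomposed with PCA. Signs of principal
components are arbitrary, so two conventions pin them: PC1 is flipped if
its loading sum is negative — quality metrics are all "higher is better",
so the quality axis should have positive loadings — and PC2 is flipped if
its NC + FFC loading sum is negative, orienting it toward mask coverage.
The overall score of a segmentation is `v1·pc1 + v2·pc2` with `v1`, `v2`
the explained-variance fractions. The score is linear in the z-scored
metrics, training scores sum to zero, and the training column mean scores
exactly zero.

Ranking across methods averages the two PC values within each imaging
modality first and across modalities second, then forms the score — so a
modality with 2 images counts as much as one with 100. A designated
baseline method (typically the bundled Voronoi segmenter) partitions the
ranking into acceptable and unacceptable methods.

The package ships no pretrained model: a quality model is always fit to
the metric matrix at hand, and the reference models used in the tests are
fit on synthetic fixtures and labelled as such. The model is fit on
per-image rows; PCs are averaged only at ranking time. For a
validation-grade model the training matrix must span a range of quality.
The test suite builds it from the ground-truth segmentation of training
fixtures under a ladder of controlled degradations (three noise levels,
two undersegmentation levels, one large shift). The Voronoi baseline is
deliberately *scored* but not used for fitting: in a small training
matrix its extreme coverage style (its cells tile the entire image)
dominates the leading component as a style contrast between methods,
which is not the quality axis the score is meant to capture.

The pairwise difference score compares two methods from their metric
vectors alone: z-score the pooled rows, take per-image element-wise
absolute differences, run a sign-fixed PCA over the difference rows of
all method pairs (self-pairs contribute all-zero rows), and report the
mean PC1 of a pair minus the PC1 of the zero row. Self-comparison gives
exactly 0 and the measure is symmetric.

## Benchmarks against a second segmentation

When two segmentations of the same image exist, `segqc` quantifies their
agreement symmetrically. Objects are matched one-to-one by Jaccard index
(JI), greedily in descending JI with deterministic tie-breaks, counting
pairs with `JI > t` as candidates. The strict inequality follows from
treating `t` as a threshold that must be exceeded; with 101 thresholds
0.00..1.00 this means identical masks score `100/101` on the
threshold-averaged F1 (the t = 1 rung admits no match) — the endpoints
are included because the average is meant to span the whole range.
F1 at `t = 0.3` is the conventional single-threshold benchmark. The
directional SEG score averages, over reference objects, the JI with the
query object covering more than half of the reference object (strictly
more; exactly half is no match); SEG′ averages the two directions so
extra unmatched objects in either mask are penalised. Greedy matching is
verified against an exhaustive one-to-one oracle in the test suite.

## Degradations and the Voronoi baseline

Four controlled degradations support sensitivity analyses:

* **Gaussian noise** (`sd` in intensity units) added per pixel and
  channel, clipped at 0 — negative fluorescence is unphysical. In a
  robustness study the noisy copy is what segmentation sees; here, where
  no third-party segmenter runs, evaluating fixed masks against the noisy
  image probes the metrics' sensitivity to image quality directly.
* **Downsampling** by a scale fraction: bilinear for intensities, nearest
  neighbour for label masks (the only label-safe interpolation), pixel
  size divided by the scale.
* **Undersegmentation**: pairs of contacting cells are merged uniformly
  at random until the cell count reaches `ceil(target · n)`; merged cells
  may not merge again, so reaching 90% of the original count means
  exactly 20% of the original cells participated. "Contacting" means
  8-adjacent after dilating each object by one pixel (pixel sets within
  Chebyshev distance 3); the merge order is random under a fixed seed.
  Nuclei of a merged pair are fused by opening the inverted nuclear mask
  around the pair with a disc whose radius is half the inter-nucleus gap
  (at least 1); the fused nucleus is kept inside the merged cell, so it
  is connected whenever the merged cell region is.
* **Shifting** all masks right and down by a fraction of the mean image
  dimension, rounded to the nearest pixel (ties up). Vacated area becomes
  background and shifted-out objects are cropped (not wrapped — wrapping
  would re-align masks with the opposite tissue edge); objects losing all
  pixels are removed together with their partners.

The Voronoi baseline thresholds the nuclear channel by Otsu, labels
8-connected components (discarding specks under 4 px, which are
threshold noise rather than nuclei), and assigns every pixel to the
nearest nucleus centroid, ties to the lower id. It tiles the whole image
with cells, needs no training, and marks the floor of acceptability for
ranked methods.

## The synthetic tissue generator

Validation runs entirely on generated fixtures. A fixture is a grid of
tiles (default 8 × 10 of 16 px at 0.5 µm/px, i.e. 80 cells in a
128 × 160 image), one elliptical cell per tile with semi-axes drawn from
6.5–8 px and jittered centres, clipped to the tile so cells never overlap
while neighbouring cells stay in contact — a confluent tissue. The grid
is rectangular on purpose: on a square lattice a 50% mask shift is a
whole multiple of the cell spacing, so shifted masks would land on other
real cells, an alignment artifact real tissue does not have. Nuclei are
concentric ellipses at 0.55 of the cell radius. Each cell gets one of 3
types; marker channels take the type's mean intensity (1000 on the
type's own marker, 200 elsewhere) scaled by a per-cell brightness factor
(SD 0.1) that emulates staining variability — and makes per-cell channel
means correlated within a type, as in real data — plus per-pixel Gaussian
noise (SD 50) over a background of 100; a dedicated nuclear-stain channel
is bright (1200) inside nuclei. Orphan cells, orphan nuclei, and
protruding nuclei can be planted at chosen fractions to exercise mask
processing. All randomness flows through one seed per call; identical
seeds give bit-identical fixtures.

What the fixtures do *not* emulate: real marker panels (tens of
channels), autofluorescence and spatial intensity texture, irregular cell
shapes and packing, spatially organised cell types, or imaging-modality
noise beyond additive Gaussian. Passing tests therefore demonstrate that
the implementation behaves as specified and that the metrics respond in
the right direction to controlled corruption; they do not certify
absolute metric values on any real modality.

A second generator produces rank-1-plus-noise metric matrices (one latent
quality factor times positive loadings) for validating the PCA
conventions in isolation.

## Validation strategy and problem sizes

The test suite checks every operation against independent oracles
(pixel-scanning brute force for overlaps and features, exhaustive
matching for benchmarks, per-threshold loops for averaged F1,
nearest-centroid scans for the Voronoi partition) on small fixtures, and
property-style invariants (symmetry, idempotence, monotonicity,
determinism) across seeded collections of fixtures. The heavier
end-to-end checks use 20-cell fixtures for mask-processing and benchmark
properties (50–100 random pairs), 80-cell fixtures for score-sensitivity
experiments (a model fit on 4 training seeds × 7 variants, tested on 20
seeds), and 100-cell fixtures for the undersegmentation accounting.
These sizes keep each metric vector computation under a quarter of a
second while leaving every effect of interest clearly measurable.

## Known limitations

* The quality score is relative to the matrix the model was fit on; scores
  from different models are not comparable, and a model fit on a
  homogeneous set of good segmentations has no quality axis to find.
* Homogeneity metrics assume multiple cell types differing across
  channels; on a uniform tissue they saturate and lose discrimination,
  and with very few channels FPCF/FPCC approach 1 regardless of quality.
* The foreground rule is global; tissues with large intensity gradients
  may need a different rule (swap `compute_foreground()`).
* Cell and nucleus shape plausibility is not scored.
* Everything is 2D; z-stacks must be segmented and evaluated per plane.
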