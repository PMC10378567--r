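---
title: "Methods: hybrid feature fusion for breast lesion CAD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid feature fusion for breast lesion CAD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusioncad)
```

This vignette is the package's account of its science: what each stage
computes, which knobs matter, which conventions were genuinely open and how
they were fixed, and what the synthetic benchmark does and does not
demonstrate.

## The problem

Breast lesions in ultrasound (US) and mammography (MG) patches are
classified benign vs. malignant. Radiologists' BI-RADS reasoning leans on
morphology — a benign mass tends to be round with a circumscribed margin,
a malignant one irregular and spiculated — alongside texture. The pipeline
encodes exactly that: shape features from a segmented lesion mask, texture
descriptors from the region of interest (ROI), generic deep features, and
a selection/fusion stage that lets two complementary selectors vote.

## Segmentation

`segment_lesion()` composes:

1. Histogram equalization. The input CDF `H(v)` maps level `v` to
   `floor(255 * H(v) / N)`. This plain CDF scaling was chosen over the
   `cdf - cdf_min` variant because it is monotone, maps a constant image to
   a single level, and leaves an already-uniform ramp fixed up to rounding.
2. A small median filter (default 3×3; window configurable to 5) to remove
   bright artifacts before thresholding. The exact window is ambiguous in
   the upstream description of this family of pipelines (3×3 in prose,
   5×5 in the summary); the smaller window preserves more boundary detail,
   so it is the default, with `segment_config(median_pre = 5)` as the
   alternative.
3. Binarization at a strict threshold (`pixel > thr`). `thr = "auto"`
   maximizes Otsu's between-class variance by exhaustive scan over all 255
   cut points. For a bimodal image any cut between the modes is optimal and
   the scan keeps the first, i.e. the lowest such cut. A featureless image
   (everything on one side of every threshold) raises "no lesion found".
4. A 9×9 median on the binary mask, then morphological hole filling:
   background not 4-connected to the image border becomes foreground. The
   "fill the gaps" step in the upstream description is undefined;
   hole-filling of the binary mask is our interpretation.
5. Suzuki–Abe border following (8-connectivity) over every foreground
   component, largest-filled-component selection (ties to raster-scan
   order), and a bounding box padded by 25 px on all sides, clipped to the
   image.

Coordinates are (row, col), 1-based in R, boxes inclusive. The tracing is
validated against a brute-force oracle — foreground pixels 4-adjacent to
outside-reachable background, per component — exhaustively on all 512
3×3 masks and on random 16×16 masks. Note that components nested inside
another component's hole are still components and are traced; the oracle
accounts for that by flooding per component.

Images with a provided mask (`mask_path` in the manifest) bypass the
automatic chain, mirroring workflows where a radiologist delineates the ROI
manually; the mask's padded bounding box still crops the ROI. This matters
in practice: rank-based equalization spreads a dominant noisy background
over the full intensity range, so Otsu on a whole low-foreground patch can
split the background rather than the lesion. The automatic chain is
intended for pre-cropped, lesion-dominated patches — which is how its
source material used it — and the segmentation acceptance check therefore
runs on noise-free synthetic patches.

## Texture descriptors

**LBP** (p = 8, r = 1): each interior pixel compares its 8 neighbors,
clockwise from the top-right, against the center; bit i (weight 2^i) is 1
when neighbor ≥ center. The printed sign rule in the source material is
self-contradictory (its equation and its worked figure disagree); the
standard ≥ convention is the default and `literal_sign = TRUE` gives the
strict-negative-difference complement. Under ≥, a constant image codes to
255 everywhere (every comparison is an equality) — the histogram is a
bijective relabeling of the alternative, so selection and classification
downstream are unaffected by the choice. The 256-bin histogram is
normalized to frequencies so ROI size does not rescale the feature.

**HOG**: central differences without the 1/2 factor (a ramp of slope 1 per
pixel has magnitude 2), unsigned orientation folded to [0°, 180°), 8×8
cells with 9 bins of 20°, and magnitude votes split linearly between the
two bins whose centers straddle the orientation (circular wrap at the
ends; a vote exactly at a bin center goes wholly to that bin). The printed
soft-assignment formulas are typographically damaged; the standard
floor-and-linear-weights split is used. Blocks of 2×2 cells slide with a
one-cell stride; each 36-vector is normalized by `v / sqrt(||v||² + ε)`,
ε = 1e−5. ROIs are resized to 128×128 by bilinear interpolation before
description — a multiple of the cell size, so the descriptor length is
fixed: 15×15 blocks × 36 + 256 = 8356 values.

**PCA**: the texture matrix is centered and its covariance
eigendecomposed — computed via the thin SVD of the centered matrix, which
yields identical components without materializing the 8356² covariance.
Unbiased 1/(n−1) scaling is used for the eigenvalues (the source mixes
1/n and 1/(n−1); the choice only scales the spectrum, never the
components). The sign of each component is fixed by making its
largest-magnitude loading positive. The default 199 retained components
cap at min(n−1, p) with a warning, so small runs degrade gracefully
instead of failing.

## Shape features

From the mask and its traced contour: area (pixel count), perimeter (the
closed Euclidean chain length: 1 per axis step, √2 per diagonal — the
printed perimeter formula is garbled and this is the only reading that
makes circularity ≈ 1 for disks), circularity 4π·Area/Perimeter², and
eccentricity. The eccentricity is implemented *verbatim* from its printed
formula, ((μ02 − μ20)² + 4·μ11)/A with raw central moments — a nonstandard
quantity (the conventional form squares μ11 and normalizes differently);
`method = "ellipse"` provides the standard ellipse-axis eccentricity for
comparison. Both are translation invariant; the verbatim form is not
scale-free, which is documented rather than silently corrected.

## Deep features

Deep features enter through a contract: `name`, `output_dim`, and a
deterministic `extract(img)`. The default extractor is a seeded stub of
width 1920 (the global-average-pool width of a DenseNet-201 backbone,
which also makes the hybrid accounting 1920 + 199 + 4 = 2123 per
modality): resize to 32×32, flatten, project through a fixed random
Gaussian map, squash with tanh. It is *not* a trained network and carries
no semantics beyond being a stable, shape-sensitive image summary; any
adapter honoring the contract (e.g. to a real pretrained CNN) drops in
without touching the pipeline. The `densenet201` name is reserved and
fails with a pointer to the stub, since no pretrained runtime ships here.

## Feature selection

**Genetic algorithm** (wrapper): individuals are binary gene strings over
the columns; fitness is mean 5-fold CV accuracy of an `rpart` decision
tree on the selected columns (empty individual scores 0). Initial
population of `population_size` (default 500) with gene probability 0.5;
each generation keeps the best μ, produces λ offspring by midpoint
crossover of two random survivors (the 50% exchange) plus independent
per-gene mutation, and applies (μ+λ) survivor selection — parents compete
with offspring, so the best fitness is monotone non-decreasing. Defaults
μ = 50, λ = 100, mutation 0.05, patience 5, 35 generations: μ/λ, mutation
and patience are not specified upstream and were fixed once at desk-scale
values; all are configurable. CV folds are drawn once per run from the
config seed, making runs bit-reproducible.

**Mutual information** (filter): per feature, I(X;Y) between the
continuous feature and the discrete label via the k-nearest-neighbor
Chebyshev-distance estimator in its mixed continuous–discrete form: the
distance to the k-th same-class neighbor defines a radius, pooled
neighbors strictly within it are counted, and digamma terms combine them
(k = 3 default; negative estimates clamp to 0; constant features score 0;
a tiny seeded jitter breaks ties). The boundary count is computed by exact
distance comparison rather than a shrunken-radius interval trick — at
float resolution the latter miscounts the k-th neighbor itself. The purely
continuous estimator core (`ksg_mi`) is validated against the Gaussian
closed form −½·ln(1−ρ²). The top 26 features are kept by default.

**Fusion** concatenates GA-selected then MI-selected columns *keeping
duplicates* — the upstream accounting (20 GA + 26 MI = 46 fused columns)
implies plain concatenation, so that is the contract; names are suffixed
`_GA`/`_MI` to stay unique.

**Balancing**: random undersampling of every class to the minority count,
without replacement, seeded.

## Classification and evaluation

The native classifier is discrete AdaBoost over exhaustive decision
stumps: ε_t is the weighted stump error, α_t = ½·ln((1−ε_t)/ε_t) with ε_t
clipped to [1e−10, 1−1e−10] so a perfect stump gets a large finite vote,
weights update multiplicatively and renormalize each round, boosting stops
at ε_t ≥ 0.5 or ε_t = 0, and prediction is the sign of the weighted vote
(exact zero → malignant, documented). XGBoost and a single-hidden-layer
MLP (`nnet`, standardized inputs) sit behind the same adapter contract
with seeded determinism; their internals are deliberately not
reimplemented.

Evaluation treats malignant as positive and reports accuracy, sensitivity,
specificity, precision, F1, Dominance = Recall − Specificity and
IBA = (1 + 0.1·Dominance)·(Recall·Specificity), per class (each class in
turn as positive) and macro-averaged. Zero-denominator metrics return NA
with a warning — silent zeros would corrupt comparisons. The Wilcoxon
rank-sum test uses pooled midranks; for combined n ≤ 10 without ties the
p-value is an exhaustive enumeration over all rank assignments, otherwise
a tie-corrected normal approximation with continuity correction (the exact
small-sample branch is what standard implementations do, and it is what
makes the test agree with brute-force permutation at tiny n).

## Synthetic data: what it emulates and what it does not

`make_lesion_image()` rasterizes an ellipse whose boundary radius is
modulated by `1 + depth·sin(count·θ)` — benign specs have zero spicules,
malignant ones at least five, so circularity separates the classes by
construction. US corruption is multiplicative uniform speckle
`I·(1 + u)`, `u ~ U(−a, a)` — the simplest multiplicative model that
exercises the median filter; MG corruption is a smooth additive gradient,
Gaussian noise, and 1–3 bright rectangles away from the lesion emulating
burnt-in view labels. At `noise_level = 0` the uncorrupted ideal (exactly
two intensity levels) is returned. Defaults — 128 px images, radius 17–36,
contrast 90, speckle amplitude 0.15 (US) and noise scale 6 (MG), 5–12
spicules of depth 0.25–0.4 — were fixed once as plausible desk-scale
conditions and are not tuned per experiment.

These images are *not* physically realistic: no acoustic shadowing, no
tissue texture, no compression artifacts, no BI-RADS density. Passing the
end-to-end benchmark (test accuracy > 0.8 on 60 lesions per class with the
stub extractor) demonstrates that the plumbing — segmentation, feature
extraction, selection, balancing, splitting, classification — is wired
correctly and deterministically, not that the system reaches any clinical
operating point. Dataset-level results on BUSI/mini-DDSM with a pretrained
backbone are expressly out of scope.

`make_planted_feature_table()` plants Gaussian columns whose class means
differ by `effect_size` noise-SDs among i.i.d. noise columns; at effect
size 3 and 200 samples per class both selectors must rank all planted
columns above all noise columns, which is the selection-stage acceptance
check.

## Numerical choices and degenerate inputs

* Median filter windows must be odd; borders replicate edges; medians are
  exact order statistics (all-row sort), matching a per-pixel sort oracle.
* Otsu ties keep the lowest optimal threshold; thresholding is strict
  (`>`).
* GA: the empty individual is assigned fitness 0; a single-feature table
  returns that feature.
* MI: `k` must be below the smallest class count.
* AdaBoost: single-class labels are rejected; if no stump beats chance the
  trainer errors rather than returning an empty ensemble.
* Stratified splitting floors the per-class test count with a 1e−9 guard
  against `0.2·n` landing just below an integer in floating point.
* Two-modality fusion pairs samples of the same class uniformly at random
  under a recorded seed — the pairing rule between modalities is an
  interpretation, since no natural sample correspondence exists.

## Problem sizes used by the test suite

The suite runs at deliberate desk scale: exhaustive 3×3 contour cases plus
50 random 16×16 masks; 8×8 oracle images for LBP/HOG; n = 5000 for the
Gaussian KSG check; 200 samples/class, 10 features for planted-subset
recovery; 1000 replicates for the rank-sum type-I rate; and 60 lesions per
class for the end-to-end run. These sizes were chosen as the smallest at
which each property is stable, and they are stated here so readers know
exactly what was exercised.
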