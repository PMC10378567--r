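# fusioncad

Computer-aided diagnosis (CAD) of breast lesions from grayscale image
patches — ultrasound (US) and mammography (MG) — for researchers who want a
fully testable, dependency-light reference pipeline for hybrid
handcrafted + deep feature fusion.

The package implements the complete chain:

1. **Segmentation** — histogram equalization, median filtering, Otsu (or
   fixed) thresholding, a second 9×9 median pass, hole filling, Suzuki–Abe
   border following to trace lesion contours, largest-component selection,
   and a 25-pixel-padded bounding-box ROI crop.
2. **Features** — Local Binary Patterns (p = 8, r = 1; 256-bin histogram),
   Histogram of Oriented Gradients (8 px cells, 9 unsigned orientation
   bins, 2×2-cell blocks, L2 normalization with ε = 1e−5), PCA reduction of
   the concatenated texture vector to 199 components, four BI-RADS-motivated
   shape features (area, perimeter, eccentricity, circularity =
   4π·Area/Perimeter²), and a pluggable deep extractor (a deterministic
   1920-wide stub ships in place of a pretrained CNN backbone).
3. **Selection and balancing** — a genetic-algorithm wrapper (binary gene
   strings, decision-tree 5-fold CV accuracy as fitness, midpoint
   crossover, per-gene mutation, (μ+λ) elitist survival) and a
   k-nearest-neighbor (Chebyshev distance) mutual-information filter in its
   mixed continuous–discrete form, fused by concatenation; random
   undersampling to the minority class.
4. **Classification and evaluation** — a native AdaBoost on decision
   stumps (ε_t, α_t = ½·ln((1−ε_t)/ε_t), multiplicative reweighting with
   Z_t normalization), plus XGBoost and MLP adapters behind one contract;
   confusion-matrix metrics including the Index Balanced Accuracy
   IBA = (1 + α·(Recall − Specificity))·(Recall·Specificity) with α = 0.1,
   and a Wilcoxon rank-sum test for per-feature class separation.

A seeded synthetic lesion generator (smooth elliptical "benign" masses vs.
spiculated "malignant" ones, with speckle for US and gradient background
plus bright label artifacts for MG) makes every stage runnable and testable
without any imaging dataset or pretrained weights.

## Worked example

```r
library(fusioncad)

# one synthetic spiculated mammography lesion
spec <- lesion_spec("MG", "malignant", base_radius = 24,
                    spiculation_count = 8, seed = 21, noise_level = 4)
lesion <- make_lesion_image(spec)
seg <- segment_lesion(lesion$image)
shape_features(seg$mask, seg$contour)
#> area 7803, perimeter 584.0, circularity 0.288
```

A smooth benign lesion with the same radius and seed scores circularity
0.932 — the roundness gap the shape features are built to expose (a disk
scores ≈ 1; boundary spicules inflate the perimeter and drive the value
toward 0).

End to end on a generated dataset:

```r
d <- tempfile()
manifest <- write_lesion_dataset(d, n_per_class = 30, modalities = "MG",
                                 seed = 8)
res <- run_pipeline(manifest, pipeline_config(
  ga = ga_config(population_size = 20, mu = 8, lambda = 16,
                 max_generations = 5, patience = 3, seed = 2)))
res$report
#> confusion (malignant positive): tp=6 tn=6 fp=0 fn=0
#>           accuracy sensitivity specificity precision f1 dominance iba
#> benign           1           1           1         1  1         0   1
#> malignant        1           1           1         1  1         0   1
#> macro            1           1           1         1  1         0   1
```

Each sample becomes a 1983-wide hybrid vector here (1920 stub deep features
+ 59 texture PCA components, capped by the 60-sample rank, + 4 shape
features); GA and MI selections are concatenated, classes are balanced by
undersampling, and a stratified 80/20 split feeds the XGBoost classifier.
The 12 held-out lesions are all classified correctly — on this synthetic
benchmark the shape contrast is strong by construction.

The same pipeline is scriptable from a shell via
`inst/scripts/fusioncad.R` (`synth`, `segment`, `features`, `select`,
`run` subcommands).

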