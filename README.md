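# histoquant

Trainable marker segmentation and spatial quantification for
histochemical / immunohistochemical (HC/IHC) slide images.

Pathology studies routinely stain serial tissue sections for different
molecular markers (CD3, CD8, CD163, Ki-67, ...) and need objective,
reproducible numbers instead of visual grading: how much of the tissue a
marker covers, how it is distributed relative to structures of interest,
and whether two markers concentrate in the same tissue volume. `histoquant`
implements that pipeline end to end for users who can annotate a few dozen
pixels per stain but have no deep-learning infrastructure:

1. **Tissue segmentation** — the slice is separated from the bright slide
   background by heavy smoothing (25 x 25 median + Gaussian sigma 0.5 on a
   downsampled gray image), Otsu thresholding, a brightness-based border
   refinement (drop mask pixels with `gL > mean_back + 0.5 * std_back`),
   morphological cleaning and cropping. Its pixel count is the tissue area
   `TA`.
2. **Marker segmentation** — a stacked, cost-sensitive rejection cascade
   DT -> DT -> RBF-SVM -> KNN(3). Each pixel is described by its RGB colour
   plus per-channel mean / standard deviation / range over n x n
   neighbourhoods (default n in {3, 7}). Training uses three annotation
   classes: marker pixels (positives), *critical* not-marker pixels whose
   colour mimics the stain (ink, blood), and rectangles of obvious
   negatives. With class counts `Npos`, `Ncrit`, `Nneg` the cost matrix is

   ```
   Cost(predict 1 | true 0) = 1 - (Nneg + Ncrit) / N
   Cost(predict 0 | true 1) = 1 - Npos / N,      N = Npos + Ncrit + Nneg
   ```

   so the minority class (almost always the positives, ratio often below
   1/50) carries the larger misclassification cost. Layers after the first
   are trained by hard-negative mining: only the obvious negatives that
   earlier layers misclassify are kept. Components below 3 px are removed
   from the final mask.
3. **Quantification** — marker density `DM_T = A_M / TA` (or over an ROI),
   normalized minimum-distance histograms from structure borders, their
   means over image sets, and histogram-intersection comparisons.
4. **Serial-section registration** — shape-based multiscale similarity
   registration of tissue masks; alignment quality is the global
   tissue-region overlap `GTRO = 100 * A(∩ T_i) / A(∪ T_i)`.
5. **Co-existence** — per section a concentration radius `R(M) =
   min(R_LIMIT, R_MAX)` is estimated from the histogram of tissue-to-marker
   distances; concentration regions are grown from cores (`distance <
   R/2`, area >= 10 (R/2)^2) expanded to `distance < R` (area >= 20 R^2).
   Pairwise measures: densities `DM_Ci = A_Mi / CA_i`, cross densities
   `DM_1InC2 = A(M1 ∩ Conc2) / CA_2`, percentages `PM_1InC2 =
   A(M1 ∩ Conc2) / A_M1`, the balance weight
   `w = min(DM_C1, DM_C2) / max(DM_C1, DM_C2)` and the weighted means
   `wMean_Dens = w (DM_1InC2 + DM_2InC1)/2`,
   `wMean_AVG = w (PM_1InC2 + PM_2InC1)/2`.

A seeded synthetic-fixture generator (`synthetic_spec()`,
`generate_section()`, `generate_serial_set()`) produces histology-like
images with exact ground truth — tissue blob, stain-coloured dots or
planted clusters, ink-like distractors — so every stage is testable without
clinical slides.

## Worked example

```r
library(histoquant)

## train a marker classifier on one annotated synthetic section
sec    <- generate_section(synthetic_spec(seed = 11))
ann    <- synthetic_annotations(sec, image_id = "img1", npos = 150, ncrit = 90, seed = 2)
planes <- compute_feature_planes(sec$image)
ts     <- assemble_training_set(annotation_set(ann), list(img1 = planes))
model  <- train_cascade(ts, seed = 3)
model
#> cascade_model: DT -> DT -> SVM -> KNN(3)
#>   layer 1 (dt): Npos=150 Ncrit=90 Nneg=3456
#>   layer 2 (dt): Npos=150 Ncrit=90 Nneg=0
#>   ...

## segment a new section and quantify
new_sec <- generate_section(synthetic_spec(seed = 99))
tissue  <- segment_tissue(new_sec$image)
seg     <- clean_marker_mask(apply_cascade(model, new_sec$image, tissue))
marker_density(seg, tissue)$percent
#> 2.23
```

On this separable fixture the first decision tree already rejects every
obvious negative (`Nneg=0` for later layers), so the critical negatives
dominate the remaining layers — the intended behaviour of hard-negative
mining. The density says 2.23% of the tissue area is covered by detected
marker; the ground truth for this section is 600 marker pixels in 26 611
tissue pixels (2.25%).

```r
## register a serial set with known transforms, then measure co-existence
tfs <- list(similarity_transform(),
            similarity_transform(15, -10, 5, 1),
            similarity_transform(-18, 6, -7, 0.97))
set3 <- generate_serial_set(synthetic_spec(seed = 301, tissue = list(radius = 80)),
                            3, transforms = tfs)
rs <- register_set(lapply(set3$sections, function(s)
  list(tissue = s$tissue, marker = s$marker)))
rs
#> registered_set: 3 sections, GTRO 54.1% -> 99.8%

coexistence_report(rs)$pairs[, c("marker_i", "marker_j", "w", "wMean_AVG_percent")]
#>  marker_i marker_j         w wMean_AVG_percent
#>        M1       M2 0.8609367          47.82118
#>        M1       M3 0.9349775          46.55646
#>        M2       M3 0.9208101          52.82891
```

Registration lifts the tissue overlap from 54% to nearly 100% and recovers
the planted translations/rotations to sub-pixel / sub-degree accuracy; the
`wMean_AVG` values then summarise how strongly each marker pair
concentrates in the same regions (here moderate, since each section drew an
independent random marker layout).

A command-line wrapper is installed with the package
(`inst/scripts/histoquant`):

```sh
Rscript inst/scripts/histoquant all --out-dir run1 --seed 4
```

runs simulate -> tissue -> train -> segment -> quantify -> register ->
coexist and writes PNG masks, CSV/JSON measures and a manifest with MD5
hashes of every artifact.

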