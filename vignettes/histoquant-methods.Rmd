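---
title: "Methods: trainable marker segmentation and spatial quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trainable marker segmentation and spatial quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histoquant)
```

`histoquant` quantifies stained markers in HC/IHC slide images. This
vignette documents the models and procedures the package implements, the
parameters that matter and their defaults, the numerical choices made where
a published description leaves room, and what the synthetic test bed does
and does not demonstrate.

## Tissue segmentation

The slide background is bright and nearly uniform; the tissue slice is
darker and textured. `segment_tissue()` exploits only that contrast:

1. The image is downsampled so its largest dimension is at most
   `downsample_limit` (default 5000 px — beyond this, finer resolution adds
   nothing to a region-level mask but multiplies the filtering cost),
   converted to gray (luminance weights 0.299/0.587/0.114) and smoothed
   with a 25 x 25 median filter followed by a Gaussian of sigma 0.5. The
   heavy median kills salt-and-pepper noise and stain texture; the small
   Gaussian removes the remaining pixel-level roughness.
2. Otsu's threshold splits the smoothed histogram; tissue is the darker
   class. A constant image (no contrast) is an error, not an empty mask.
3. The mask is rescaled to full resolution (nearest-neighbour, preserving
   binarity) and refined: with `mean_back`/`std_back` the mean and standard
   deviation of the full-resolution gray values outside the mask, every
   mask pixel with `gL > mean_back + 0.5 * std_back` is dropped. We apply
   the intensity test to *all* mask pixels rather than only a border band:
   the brightness criterion itself selects the false positives, which
   concentrate at the border; any interior punch-through is repaired by the
   subsequent hole filling. The operation is anti-extensive and, for fixed
   statistics, idempotent.
4. Cleaning: holes up to `hole_fill_frac` (default 1%) of the tissue area
   are filled; connected components are removed when their area is below
   `min_area_frac` (default 0.05%) of the image or their compactness
   `4 pi A / P^2` falls below `min_compactness` (default 0.05). The
   perimeter `P` is the count of pixel edges between foreground and
   background, so a 1-px filament of length L has `P ~ 2L` and compactness
   `~ pi/L` — long spicules are removed, convex blobs (compactness ~ 0.6
   digitally) are far from the threshold. These three thresholds have no
   canonical published values; the defaults were fixed once against the
   synthetic test bed and are exposed as arguments.

## Pixel features

Each pixel carries its RGB colour plus, per neighbourhood size n, the
per-channel mean, *population* standard deviation, and range over the n x n
window, with replicate padding at borders (both conventions are
implementation choices; the population/sample difference is negligible at
n = 7 but tests pin it down). The default size list c(3, 7) yields
3 + 9 x 2 = 21 dimensions; `sizes = 7` yields the minimal 12-feature set.
The size list is stored inside trained models so training and prediction
can never disagree. Window statistics are computed exactly with integral
images (mean/sd) and separable running extrema (range), and per-tile
computation with an overlap of `max(sizes) %/% 2` pixels reproduces
whole-image values bit for bit — the property that makes strip-wise
processing of large slides exact rather than approximate.

## Training data and cost model

Three annotation classes mirror what an annotator can realistically
provide: individual marker pixels (positives), individual *critical*
not-marker pixels whose colour mimics the stain, and rectangles containing
only obvious negatives. Rectangles expand to pixel sets lazily; a pixel
annotated positive wins over membership in a negative rectangle
(disjointness by construction). Typical sets are heavily unbalanced —
hundreds of positives against tens of thousands of rectangle pixels, a
ratio at or below 1/50 — so classification is cost-sensitive: with class
counts `Npos`, `Ncrit`, `Nneg` and `N` their sum, misclassifying a true
positive costs `1 - Npos/N` while a false positive costs
`1 - (Nneg + Ncrit)/N`. The off-diagonals sum to 1 and the minority class
always carries the larger cost. The KNN layer is deliberately
cost-neutral.

## The classifier cascade

Four layers in fixed order — decision tree, decision tree, RBF SVM, KNN
with K = 3 on raw RGB — applied as a rejection cascade: a pixel must be
accepted by all four to count as marker. Training:

* **Layer 1 (DT)** sees everything. Ten candidate trees are grown; each on
  `ceiling(Npos/10)` random positives and
  `min(ceiling((Nneg + Ncrit)/10), 5 Npos)` random negatives, validated on
  all remaining samples; the candidate with the best plain validation
  accuracy wins (ties to the first). Cost-sensitivity enters through the
  loss matrix of `rpart`.
* **Hard-negative mining**: the obvious negatives the chosen tree
  misclassifies (its false positives) are the only obvious negatives the
  next layer sees; all positives and all critical negatives are always
  kept. Mined sets are nested layer over layer by construction.
* **Layer 2 (DT)** repeats the 10-fold procedure on the reduced set.
* **Layer 3 (SVM)** uses the same fold machinery with 2 folds. C and gamma
  are selected on a small grid (C in {1, 10, 100}; gamma in {1/(d Var(X)),
  0.01, 0.1}) inside each fold by training accuracy; the fold winner is
  chosen by validation accuracy. Cost-sensitivity enters through class
  weights proportional to the cost-matrix off-diagonals — the
  expected-loss-equivalent formulation, since no particular mechanism is
  canonical. Obvious negatives entering the SVM are capped at `20 Npos` by
  seeded subsampling to bound the kernel computation on degenerate
  configurations.
* **Layer 4 (KNN)** stores positives, criticals and the SVM's surviving
  false positives as RGB triples; prediction is a 3-nearest-neighbour vote
  (no ties are possible with two classes and K = 3; equidistant neighbours
  are all included, deterministically).

If mining empties a layer's obvious negatives the layer trains on
positives + criticals only, with a warning — on cleanly separable stains
this is the expected outcome, not a failure. The raw marker mask is cleaned
by removing 8-connected components of fewer than 3 pixels. Trained models
serialize with their feature configuration, seed and per-layer counts;
construction environments are stripped so equal seeds give byte-identical
model files.

On the two-Gaussian colour fixture (marker mean (180, 60, 50) vs ink-like
distractor (120, 60, 50), shared sd 12) the cascade reaches held-out pixel
F1 >= 0.95, and annotating distractor pixels as critical negatives holds
the distractor false-positive rate at or below 1% — the test the fixture
was designed to make meaningful, since the two classes overlap only in
colour space.

## Densities and distance histograms

`DM_T = A_M / TA` (reported as a percentage) with the ROI variant
`A_{M ∩ ROI} / ROIA`. Minimum-distance histograms use the exact Euclidean
distance transform, bins `[k w, (k+1) w)` of width `w` (default 1 px), an
optional band limit excluding far pixels, and normalization over the
included pixels. Means over image sets weight each image's normalized
histogram equally (mean of histograms, not a pixel pool). The histogram
intersection `sum_i min(a_i, b_i) / sum_i b_i`, averaged over both
directions, compares two histograms; for normalized inputs it equals the
plain min-sum, lies in [0, 1], and equals 1 exactly at equality.

## Serial-section registration and GTRO

Serial sections of one block have similar but not identical outlines, in
arbitrary position and orientation. `register_pair()` aligns binary tissue
masks with a similarity transform (translation, rotation, isotropic scale
— glass-mounted sections do not shear or deform at the scale of interest):
a pyramid halves resolution until the largest dimension is at most 256 px;
initialisation uses the centroid offset, the principal-axis angle
difference (both polarities, plus 0, scored and the best kept) and the
square root of the area ratio; each level then hill-climbs over
(tx, ty, theta, scale) with halving steps. The search objective is a *soft*
Dice: the moving mask is warped with bilinear interpolation, so fractional
edge coverage makes the objective smooth in sub-pixel shifts and
sub-degree rotations, which plain binary Dice (piecewise constant) cannot
resolve. Final masks are always warped nearest-neighbour to stay binary,
and the result is accepted only if the full-resolution overlap is at least
that of the identity — so registration can never worsen alignment;
`register_set()` additionally falls back to identity if the set-level GTRO
would drop. Alignment quality is
`GTRO = 100 A(∩ T_i) / A(∪ T_i)` over all masks of the set.

Rotation recovery is only meaningful for anisotropic shapes: a circularly
symmetric mask is invariant under rotation about its centre, making theta
unidentifiable (overlap stays perfect at any angle). The synthetic tissue
blob therefore has a default elongation of 1.25 (major/minor axis ratio,
random orientation) — also the realistic choice, since tissue slices are
rarely circular. On such shapes the recovery experiment (translations up to
30 px, rotations up to 10 degrees, scale 0.95–1.05) recovers transforms
well within 2 px / 1 degree / 0.02 scale.

## Concentration regions and co-existence

A section's concentration radius is estimated from the histogram (1-px
bins `[r, r+1)`, strict inequalities throughout) of distances from every
tissue pixel to the nearest marker pixel. `R_MAX` is the centre of the
first maximal bin — the most common tissue-to-marker distance, which in
sections with scattered markers reflects their typical half-spacing.
Sections without real concentrations push the peak far out, so `R_LIMIT`
caps the radius: the largest integer r such that fewer than `50 A_M`
pixels lie at distance < r. `R = min(R_LIMIT, R_MAX)`, floored at 1 px.
Regions are then built in four steps: core pixels at distance < R/2; core
components below `10 (R/2)^2` px deleted (a disc around an isolated dot
has area `pi (R/2)^2 < 10 (R/2)^2`, so singleton dots never found a
region); surviving cores expanded to the connected components of
{distance < R} that contain them (expansion cannot leak into sparse areas
that never had a core); expanded components below `20 R^2` px discarded.
Ties in `R_MAX` go to the smallest distance, biasing toward tighter
regions; the distance map is computed within the tissue only.

Given registered sections with markers `M_i` and region sets `Conc_i`
(section-total area `CA_i`; the per-region breakdown is also emitted), the
measures are `DM_Ci = A_Mi / CA_i`,
`DM_1InC2 = A(M1 ∩ Conc2) / CA_2`, `PM_1InC2 = A(M1 ∩ Conc2) / A_M1`,
`w = min(DM_C1, DM_C2) / max(DM_C1, DM_C2)`, and the symmetric summaries
`wMean_Dens = w (DM_1InC2 + DM_2InC1)/2` and
`wMean_AVG = w (PM_1InC2 + PM_2InC1)/2`. Measures with a zero denominator
are reported as `NA`, never as 0 — zero would assert "no co-existence",
a different claim from "not measurable". An ROI clips every mask and
region and replaces the tissue area by the ROI area.

## The synthetic test bed

`generate_section()` renders: a near-white background (Gaussian noise sd 4
per channel, salt-and-pepper at 1e-4 — the noise types the smoothing stage
targets), an elongated wobbly tissue blob with a flat tint, marker dots
(uniform or Gaussian-clustered with optional sparse background dots) drawn
from the marker colour model, and ink-like distractor blobs hugging the
tissue border. Ground truth is exact by construction and every draw is a
deterministic function of the seed.

For the concentration-region experiment the layout combines two dense
clusters (intra-cluster spacing ~4 px) with sparse background dots
(spacing ~12 px): the background spacing sets the histogram mode and hence
R (~5–6 px), the cores then merge cluster dots but the isolated background
cores die in the area filter — exactly the mechanism that separates
"concentration" from "scatter" on real slides.

What passing on this bed shows: the implemented operators satisfy their
definitions (oracle-checked against brute force), the cascade separates
colour-defined classes under the stated noise, registration recovers
similarity transforms, and the geometric machinery extracts planted
concentration structure. What it does not show: performance on real
histology — real stains have texture, uneven illumination, out-of-focus
regions and colour variation between scanners that a flat-tint generator
deliberately omits; real sections deform non-rigidly; real marker objects
are cells, not discs. The package's accuracy claims on clinical material
must come from annotation-and-retrain loops on that material.

## Numerical and design notes

* Connectivity is 8-connected for foreground components throughout
  (4-connected for background holes); distances are exact Euclidean.
* "Distance less than" is implemented as strict inequality everywhere.
* Downsampling uses bilinear interpolation; mask up/downscaling uses
  nearest-neighbour.
* Tiling is vertical-strip with a default overlap of 3 px (the radius of
  the 7 x 7 feature window) so tiled and whole-image results agree
  exactly; the per-tile pixel budget is configurable (default 25e6).
* Overlay backgrounds default to black (maximal contrast for additive
  colours); white is available.
* Problem sizes in the test suite: sections 256–320 px, 50-image Dice
  sweeps, 30 registration recovery cases, 1000-tuple GTRO oracle — chosen
  so the whole suite settles in a few minutes on one core while still
  exercising each mechanism at a scale where its failure modes (component
  merging, histogram ties, plateau stalls) can occur.
* The cross-validation "accuracy" used for candidate selection is plain,
  unweighted validation accuracy; grid selection inside an SVM fold uses
  training accuracy. Both are deliberate, simple readings; the cascade's
  quality is guarded by the end-to-end recovery tests rather than by the
  selection criterion.
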