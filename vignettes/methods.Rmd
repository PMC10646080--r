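---
title: "Methods: organoid segmentation, morphometry and growth analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organoid segmentation, morphometry and growth analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Brightfield monitoring of organoid cultures produces images in which cystic
organoids appear as bright, roughly ellipsoidal regions with a darker rim,
on a noisy and unevenly illuminated background. Out-of-focus organoids at
other depths of the 3-D matrix appear as blurred low-contrast blobs and must
*not* be measured. The package turns such a frame into per-organoid
morphometry and per-well culture parameters in five stages: segmentation by
a convolutional network, morphological cleaning, ascending-order contour
labeling, object selection, and shape measurement with micron calibration.
Downstream analytics relate per-image parameters to well viability readouts
and flag when a culture's growth slows enough to warrant subculture.

## Segmentation model

The network is a U-Net whose convolutional blocks are *multi-scale residual
blocks*: two parallel branches with 3×3 and 7×7 kernels (each followed by
per-channel normalization and ReLU), concatenated and fused by a 1×1
convolution, plus a residual shortcut that is 1×1-projected when the input
and output channel counts differ. Downsampling is 2×2 max pooling; upsampling
is nearest-neighbour followed by a 1×1 channel projection; the decoder
concatenates the encoder skip at each level; a final 1×1 convolution and
sigmoid produce a per-pixel organoid probability. Channels double per level
(`base_channels` at the first level). The 3/7 kernel pair makes each block
sensitive to both fine rims and coarse organoid bodies in one pass, which is
what makes small-organoid segmentation workable at modest depth.

The implementation is native R: convolutions are evaluated as sums of
shifted BLAS matrix products, and every backward pass is the hand-derived
adjoint of its forward computation, verified against central finite
differences in the test suite. There is no external deep-learning runtime;
the trade-off is speed, which the reduced problem sizes below respect.

Two deliberate choices:

* **Per-sample (instance) normalization** instead of batch normalization
  inside blocks. Gradients are accumulated per sample in this
  implementation, and instance normalization makes inference deterministic
  and exactly consistent with training statistics without running-moment
  estimation — valuable for bit-reproducibility contracts. It also absorbs
  the illumination differences between frames.
* **Whole-frame inference with reflect padding** to the next multiple of
  `2^depth`, rather than tile-and-stitch: segmentation time stays a few
  seconds per frame and no seam artifacts arise.

Binarization uses a strict `prob > threshold` comparison at a symmetric
default of 0.5 (exposed as a flag); an exactly-0.5 map — e.g. from a zeroed
head — therefore yields an empty mask.

## Training

The trainer's full-scale defaults are the regime this kind of organoid
segmentation model is typically trained under: random square crops (512
default), random flipping, rotation, affine transformation and Gaussian
blurring as augmentation, minibatches of eight, stochastic gradient descent
at learning rate 0.001, and the compound objective

L_total = L_CE + L_Dice

with unit weights: mean binary cross-entropy (probabilities clipped to
(1e-7, 1-1e-7)) plus soft dice loss with smoothing 1 (so a perfect
prediction scores ≤ 1/(2|G|+1) rather than exactly 0). Momentum (0.9) and
the augmentation magnitudes (flip p = 0.5 per axis, rotation ±180°, scale
0.9–1.1, translation ≤ 10 %, blur σ ∈ [0, 1.5]) are package defaults, all
configurable. Geometric transforms are applied
identically to image and mask, with nearest-neighbour resampling for the
mask so it stays binary; blur touches the image only. Per epoch one random
crop is drawn per training image; after each epoch the mean dice coefficient
of thresholded predictions on the validation set is recorded, and the
returned weights are those of the best-validation epoch.

**Reduced-scale configuration.** The test suite and the acceptance script
train a width-reduced model (depth 2, 8 base channels) on 15 synthetic
256×256 scenes with 128-pixel crops, validating on 5 and testing on 10 —
mirroring a realistic 15/5/10 dataset design at full scale. At this reduced
scale the full-scale learning rate of 0.001 converges far too slowly to be
useful; the reduced configuration uses SGD at 0.05 with momentum 0.9 for 12
epochs, which reaches a stable validation plateau on the synthetic regime.
`train_config()` keeps the full-scale defaults.

## Synthetic scenes as ground truth

`generate_scene()` emulates exactly the regime the pipeline targets:

* in-focus organoids: bright interior (+45 intensity units over a
  background of 115), dark rim (−60, 2.5 px wide), sizes from a truncated
  lognormal in microns (default median 110 µm in [30, 350] for 512² frames;
  the 256² study scenes use median 60 µm in [25, 120]), eccentricities
  uniform in [0, 0.7–0.8), non-overlapping bounding-circle layout;
* out-of-focus distractors: the same shapes at low contrast (+14), blurred
  with σ = half their minor semi-axis — rendered in the image but *excluded*
  from the ground-truth mask, exactly as annotation excludes unrecognizable
  out-of-focus organoids;
* Gaussian pixel noise (σ = 7) and a mild linear illumination ramp (±8).

The truth mask is the exact union of the in-focus ellipse rasterizations,
including border-cropped and sub-40 µm objects — the selection filters are a
downstream, testable stage. Each rendered entity carries its analytic area
πab and eccentricity √(1 − b²/a²), which is what makes the generator an
oracle for the morphometry and detection code. `(config, seed)` determines
every scene bit-identically.

What the generator does **not** model: budding/crypt morphologies,
overlapping organoids with contact junctions, Matrigel texture, vignetting,
or real camera noise. Passing tests therefore demonstrate correctness of the
pipeline's machinery on the cystic-organoid regime, not performance on any
particular microscope's data. Overlapping organoids are a known failure
mode of the approach and are deliberately out of scope.

Growth series scale every semi-axis by √g per day so areas scale by g,
with an optional plateau day after which g drops (default 1.05) — emulating
the growth slow-down that marks subculture readiness. Well viability is
k · (total analytic organoid area) · (1 + ε), ε ~ N(0, noise²), which by
construction makes total projected area the only parameter exactly
proportional to viability.

## Post-processing and selection

`clean_mask()` applies opening-then-closing with a 3×3 elliptical
(cross-shaped) structuring element for `iterations` rounds (default 2, an
empirical choice, exposed as a parameter), fills all enclosed
background holes, and removes components under `min_area_px` (default 50) —
a *noise* threshold distinct from the biological filter. The operation is
idempotent at fixed parameters, which the tests assert directly.
Componentry is 8-connected throughout; labels ascend in raster order of
each component's topmost-then-leftmost pixel (a fixed convention, since
"ascending order" alone does not pin one down). `filter_objects()` then
drops objects touching any border and objects with equivalent diameter
under 40 µm — "size" is interpreted as equivalent-circle diameter
√(4A/π), the least shape-dependent of the candidate diameters. Coordinates are 1-based
(row, col), R's native convention.

## Morphometry

Nine metrics per organoid: projected area (pixel count), equivalent
diameter √(4A/π), perimeter, major/minor axis lengths from the
second-central-moment equivalent ellipse, eccentricity √(1 − (minor/major)²),
circularity 4πA/P², roundness 4A/(π·major²), and solidity A / convex-hull
area. Calibration multiplies lengths by µm/px and areas by its square;
dimensionless metrics are unit-free. Calibration is always a configured
value — inferring it from a burned-in scale bar is error-prone OCR and out
of scope.

Numerical conventions, chosen against analytic ellipse oracles:

* **Perimeter** is the traced closed-boundary chain length with
  bias-corrected step weights (0.948 axial, 1.340 diagonal,
  Vossepoel–Smeulders). Naive √2 weighting overestimates smooth perimeters
  by ~5 %, which would bias circularity on a digitized disc to ~0.90; the
  corrected weights keep disc circularity within a few percent of 1.
  Circularity and roundness may still exceed 1 slightly on digitized discs;
  no clamp is applied.
* **Solidity** uses the convex hull of boundary pixel centers with the
  ratio clamped at 1: the center hull under-bounds the pixelated region by
  a half-pixel rim, so convex digitized shapes score exactly 1 while
  genuine concavity is still detected.
* Degenerate inputs: an empty region is an error; a zero-length boundary
  yields NA circularity rather than a division by zero.

Tolerances documented from the oracle suite: area within 2 % of πab,
axes within 3 %, eccentricity within 0.05, for semi-axes of 15 px and up.

## Evaluation and statistics

Segmentation is scored by the dice similarity coefficient, with both raw
and post-processed predictions reported (cleaning can trade a little DSC
for cleaner objects). Two empty masks score 1 (vacuous agreement).

Detection matches predicted objects to ground-truth instances greedily by
descending pairwise IoU, one-to-one, at a default threshold of 0.5 — the
field-standard convention, exposed as a flag since detection confusion
matrices are rarely reported with their matching rule.
Negatives are annotated non-organoid instances (the synthetic distractors):
an unmatched negative is a true negative, a prediction matching a negative
(or nothing) is a false positive. This TN definition is a documented
divergence risk against any external dataset that defines negatives
differently.

Agreement statistics: Lin's concordance correlation coefficient (original
n-denominator moments; CI via Fisher z with Lin's asymptotic variance),
Pearson r with the t-based two-sided P, and OLS with R². Pearson and OLS
delegate to `stats::cor.test`/`stats::lm`; CCC is implemented here and all
four are pinned to independent brute-force oracles at 1e-10 in the tests.
Zero-variance inputs are flagged as undefined rather than propagating NaN;
|CCC| ≤ |r| holds on every input.

## Growth analytics

Per-day series are normalized per replicate to Day 1 (relative value 1),
then averaged across replicates (mean ± SD). The subculture time point is
operationalized as the first day whose day-over-day relative growth falls
below `slowdown_fraction` (default 10 %) — an operational rule defined by
the package, with the threshold exposed, since "growth has slowed" is
otherwise a judgment call. The flag is monotone in the threshold. Parameter/viability
correlation ranks every numeric per-well parameter by Pearson r against
viability; on the synthetic plates total projected area is top-ranked by
construction.

## Problem sizes

The test suite and the acceptance script use: 256×256 scenes for the
15/5/10 end-to-end experiment (depth-2, 8-channel model, 12 epochs,
128-pixel crops); 28 scenes for the count/area agreement study; 90 wells
across 5 days for the viability correlation; 18 wells over a two-fold
six-level serial dilution for the regression; 5-day triplicate series for
the subculture flag; 64×64 scenes for fast training smoke tests. These
sizes were chosen as the smallest at which the studied effects are
comfortably resolved on a single CPU.

## Known limitations

* Touching or overlapping organoids are segmented as one object; no
  instance splitting is attempted.
* The trained network transfers only within the imaging regime it was
  trained on; the synthetic regime is deliberately simple.
* Discretized perimeter (hence circularity) carries residual bias below
  ~10 px radius; the selection filter removes most such objects anyway.
* CCC's confidence interval is asymptotic and unreliable for n below ~10
  or |CCC| near 1.
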