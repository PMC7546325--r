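---
title: "Measuring stomatal pores in slide-scanner micrographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring stomatal pores in slide-scanner micrographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomapore)
```

## The problem

Stomata — paired guard cells enclosing a central pore on the leaf
epidermis — regulate gas exchange, and their aperture is a direct readout
of plant water status. Nail-polish imprints of the leaf surface imaged on
a brightfield slide scanner yield whole-sample micrographs containing
thousands of stomata, far too many to measure by hand. `stomapore`
implements an automated pipeline for such images: locate every stomate,
then measure its pore area in square microns.

Two properties of slide-scanner imprint imagery drive the design. First,
focus varies across the sample because the imprint surface is uneven, so
image sharpness is spatially non-uniform. Second — and central to this
package — the pore of a stomate may appear either *darker* or *lighter*
than its surrounding guard cells depending on where the focal plane sits
relative to the pore. Any measurement algorithm tuned to one polarity
silently fails on the other; the pore estimator here detects the polarity
per stomate instead of assuming it.

## Detection model

Detection is sliding-window patch classification. A square window
(default 96 px, about 24 µm at the default scale of 0.25 µm/px — a
typical stomate span) is slid across the image at a fixed stride; each
window is described by a gradient-orientation histogram and classified by
a quadratic-kernel support vector machine into **stomate**, **vein** or
**background**. The vein class exists to absorb the negatives most easily
confused with stomata — elongated dark venation — mirroring three-class
training-set designs used for this problem. Large scans are first cut
into overlapping tiles (default 2048 px with 128 px overlap, at least one
window) that are classified independently and reassembled, with the
stomate class winning wherever tiles disagree: a stomate found by one
tile is never erased by a neighbour's background, and duplicates merge
downstream in connected components.

The descriptor is deliberately weights-free so the package builds and
tests without any pretrained network: the window is divided into an
8 × 8 cell grid, each cell accumulating a magnitude-weighted histogram of
unsigned gradient orientations (9 bins over [0°, 180°)), and the
concatenated 576-vector is L2-normalised *as a whole*. Whole-vector
normalisation matters: per-cell normalisation would equalise faint
epidermal-cell outlines with strong guard-cell edges and, in our
validation, roughly halves patch accuracy. A deep-feature backbone can be
substituted through the same extractor contract if one is available.

Each window position paints only its central stride-sized cell with the
predicted class ("central-cell painting"), keeping localisation crisp;
whole-window voting exists behind the `paint` config flag but in our
experiments the classifier fires only when a stomate is near the window
centre, so voting starves recall. The stride default is 12 px: the
painted-cell granularity bounds how tightly a detection box can fit a
stomate, and with 24–56 px stomata a coarse stride (e.g. 48 px) snaps box
edges by up to ±24 px, which no downstream step can undo. Finer strides
cost proportionally more windows; 12 px is the coarsest setting that
left box geometry limited by the classifier rather than the grid.
Stomate-class components of at least `min_region_px` (default 432 px²,
three stride cells — isolated single-window misfires fall below it)
become boxes: the component's bounding rectangle dilated by 8 px, scored
by the fraction of the box the component covers.

### Training data and hard negatives

Classifiers are trained on patches sampled from synthetic scenes (below):
stomate patches centred on true stomata with a small jitter, vein patches
centred on vein pixels, background patches with zero stomate pixels. One
sampling decision proved decisive: background windows keep only their
*central cell* clear of veins, and half of them are deliberately centred
a short distance (24–40 px) off a vein. Without these hard negatives the
training set contains no example of "a vein crossing the window
off-centre" — vein patches have centred veins, plain backgrounds have
none — and the classifier extrapolates that configuration to "stomate",
producing chains of false boxes alongside every vein. Localisation in
sliding-window detection is learned from exactly such off-centre
negatives. The SVM additionally up-weights the two negative classes
(1.5 : 1): a negative window misread as stomate seeds a false box,
whereas one missed window of a true stomate is recovered by its
neighbours. Training draws patches from six scenes by default — vein
shape variety across scenes matters more than patch count per scene.

## Pore-area estimation

Each detection box is cropped with a 25 % margin and measured
independently through a fixed chain; every failure path is a status, not
an error:

1. **Enhance.** CLAHE on the luminance (clip limit 2, 8 × 8 tile grid,
   tiles never smaller than 16 px — smaller tiles over-amplify flat
   texture), a global linear stretch to [0, 255], then an unsharp mask
   (σ = 2 px, amount 0.5). A constant patch passes through unchanged.
2. **Binarise.** Otsu's threshold (integer, ties broken toward the
   smallest threshold so results are reproducible). The foreground is
   whichever side of the threshold covers *less* area: a stomate is a
   minority structure in its patch, and this choice — rather than a fixed
   "dark side" convention — is what keeps the chain symmetric between
   dark and light pores.
3. **Filter.** 8-connected components no larger than 50 px² are dropped
   as dust and air bubbles.
4. **Select.** Among components whose centroid falls in the central 50 %
   box of the patch, the largest wins (ties to the most central), and
   components covering a quarter or more of the patch border are excluded
   outright — epidermal-wall webs span the whole patch, so they pass the
   centroid test while clearly not being the stomate. A correct detection
   centres the stomate, so edge shapes are rejected here; no qualifying
   component means `no_detection`.
5. **Align.** The patch is rotated by minus the region's major-axis
   orientation (second-moment estimate) with canvas expansion — bilinear
   for intensities, nearest-neighbour for the mask. Nearly circular
   regions (axis ratio < 1.05) skip rotation. The rotation canvas is
   filled with the patch mean, which no pore can absorb during growth.
6. **Cross-section.** Intensities are read down the column through the
   mask centroid, clipped to the mask's vertical extent plus 2 px,
   smoothed by a centred 3-sample moving average. Local extrema need
   topographic prominence of at least 5 % of the profile range; runs of
   equal values are compressed first, because a flat-bottomed pore has no
   *strict* local minimum and would otherwise be invisible.
7. **Locate the pore centre.** The extremum nearest the centroid is the
   pore centre: a valley means a dark pore, a peak a light one. An exact
   distance tie goes to the more prominent extremum, then to the valley.
8. **Grow.** Flood fill (8-connected) from the pore centre accepts pixels
   whose intensity differs from the seed by at most half the chosen
   extremum's topographic prominence — half-depth (FWHM-style)
   segmentation. The tolerance scales with the pore's own depth against
   its guard-cell shoulders rather than with the whole profile range:
   on a sharply focused pore the two coincide, but when blur turns the
   pore edge into a gradient, half-depth keeps tracking the true
   boundary where a fixed range fraction recovers only the pore core.
9. **Sanity checks.** The grown pore is rejected — with a reason code —
   if it covers half or more of the patch border (the fill escaped), if
   it outgrows the stomate mask, or if its centroid falls outside the
   *hole-filled* stomate mask. Filling matters: for a light pore the
   binarised stomate is the dark guard-cell annulus, a ring that never
   contains the pore centre itself.

Accepted pores report `area_um2 = area_px × pixel_scale²` exactly. One
normalisation precedes everything: a patch whose mean intensity is below
mid-grey is treated as a photographic negative and inverted before
processing (brightfield imprints have bright backgrounds), with the
reported polarity mapped back. This makes the whole chain exactly
equivariant under intensity inversion instead of approximately so —
CLAHE is not inversion-symmetric on its own.

The rejection statuses operationalise "no confident prediction"; real
pipelines on slide-scanner data reject a comparable fraction of detector
output (false positives with no discernible pore), and those rejections
are counted as no-detections in the accuracy bookkeeping.

## Evaluation protocol

Detection is scored by grid discretisation of box annotations: the manual
mask (union of true bounding boxes) and the automatic mask (union of
detected boxes) are discretised onto square cells — a cell counts as
stomate when at least half its pixels are — and TP/FP/FN/TN are counted
cell-wise. Precision, recall and the F-score (harmonic mean, reported to
5 decimals) follow, with per-image rows averaged *unweighted* into
summary metrics; that averaging scheme is the one consistent with the
published benchmark table this package bundles
(`detection_benchmark()`). The evaluation cell defaults to 16 px: the
cell must resolve the smallest object of interest, and with 24–56 px
stomata a cell as large as the detection stride window would never reach
50 % occupancy from a true stomate, making recall undefined.

Pore accuracy is bookkept per source: `available = total −
no_detections`, `correct = available − incorrect`, and a percentage to
two decimals. Both no-detections and rejected-with-reason estimates count
as no-detections. On synthetic data the correctness flag is IoU ≥ 0.5
between the estimated and true pore masks — a concrete reading of
"considerable mismatch" judgments that are qualitative on real data. Two
summary bases are reported because they genuinely differ (pooled
correct/available versus mean of per-row percentages); the bundled
benchmark table (`pore_benchmark()`) exhibits exactly this ambiguity.

## The synthetic scene generator

Real validation imagery for this problem is not generally available, so
the package generates its own scenes with exact ground truth
(`generate_scene()`). A scene is a pure function of its spec, including
the seed. It emulates, in rendering order: a low-contrast polygonal
epidermal-cell texture (jittered-grid Voronoi cells, outlines 8 intensity
levels below background — pavement-cell walls in imprints are much
fainter than guard cells; cell scale 80 px ≈ 20 µm); dark curved veins
(quadratic Bézier strokes); small dust/bubble artifacts; then the stomata
themselves. Each stomate is an ellipse (major axis 24–56 px, aspect
0.45–0.65, uniform orientation): a guard-cell annulus between the outer
ellipse and an inner ellipse at 80 % axes, and a pore rendered as a
*lens* — the intersection of two circles offset along the minor axis —
sized half the inner axes, matching the eye-shaped pores seen in
brightfield imprints. Polarity is an intensity swap only (dark pore 70,
light pore 230, guard 140, background 180): the underlying cause is the
focal plane, which we do not physically model. Blur and noise are applied
*after* the masks are recorded, so ground truth stays exact: a smooth
random σ field (4 × 4 grid, bilinearly upsampled, range 0.5–1.5 px by
default) blends two Gaussian-blurred anchor images — an approximation of
true per-region blur — followed by additive Gaussian noise (σ = 3
levels).

What passing on these scenes does and does not show: the generator
reproduces the geometry, polarity dichotomy, focus variation and
clutter classes of imprint micrographs, but not imprint deformation,
staining variability, species-specific guard-cell morphology, or the
continuous texture spectrum of real epidermis. Synthetic results
validate the *mechanics* of the pipeline — polarity robustness,
localisation, bookkeeping — not field accuracy on any particular
species.

## Numerical choices and degenerate inputs

* All connectivity is 8-connected, everywhere (components, flood fill);
  the base labelling is 4-connected and diagonal adjacencies are merged
  by union–find, renumbered in row-major first-pixel order for
  reproducibility.
* Otsu requires at least two distinct grey levels; a constant patch maps
  to `no_detection` upstream.
* Rotation uses an explicit inverse-mapping warp whose forward transform
  is retained, so pore masks are resampled back to patch coordinates
  exactly (nearest-neighbour), rather than by composing two lossy
  rotations.
* A region filtered to exactly the area cutoff is removed ("no larger
  than" is read strictly).
* Box coordinates are 0-based half-open `[row0, row1) × [col0, col1)`,
  so area is exactly `(row1 − row0)(col1 − col0)`.
* The pipeline's measurement path contains no randomness; given an
  image, a model and a config, result files are byte-identical across
  runs. Training is seeded (feature extraction is deterministic and the
  SVM fit is seeded).

## Problem sizes used in validation

The test-suite and acceptance runs use 960 × 960 px scenes with 20
stomata each — at 0.25 µm/px a 240 µm field, giving realistic stomatal
spacing — with six training scenes (150 patches per class) and ten
held-out evaluation scenes. Pore-recovery checks use 256 px two-stomate
scenes, 50 clean stomata for the polarity suite and 20 moderately
blurred (σ = 2 px) stomata for the degradation check. These sizes were
chosen to exercise every code path at realistic densities.

## Known limitations

* Stomata smaller than about 30 px major axis have pores near the 50 px²
  floor; the grown region under-covers their sharpen-halo edges and IoU
  against truth degrades first there.
* When an epidermal wall fuses with the guard-cell annulus in the binary
  image, the mask centroid shifts and the nearest cross-section extremum
  can be a guard-cell valley rather than the pore — polarity is then
  misread. This affects roughly one stomate in fifty even on clean
  synthetic renders and is the dominant failure mode of the measurement
  chain; it is the synthetic counterpart of the wall-interference errors
  the method exhibits on real micrographs.
* The detector's precision depends on the variety of vein hard negatives
  seen in training; with few training scenes an unlucky draw can leave
  vein configurations that still fire (see the training-data section).
* Aperture width/length decomposition, guard-cell segmentation and
  open/closed classification are out of scope; the pipeline measures
  pore area only.
* The discretised evaluation is resolution-dependent by design; compare
  runs only at the same cell size.
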