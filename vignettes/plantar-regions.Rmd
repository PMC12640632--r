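---
title: "Segmenting plantar pressure images into anatomical regions"
author: "plantarseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting plantar pressure images into anatomical regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantarseg)
```

## The problem

A standing person leaves a pressure footprint on a sensor plate: an 8-bit
grayscale image in which intensity encodes pressure (here 1 intensity unit
≙ 1 kPa by default, adjustable via `pressureScale`). Clinical and footwear
applications need that footprint divided into functional regions — the
forefoot (propulsion), the midfoot or arch (shock absorption) and the heel
(load bearing), with the forefoot further split into its lateral (outer)
and medial (inner) halves. Manual annotation is slow and inconsistent, and
learned segmenters need labelled data that rarely exists for a given
device. The approach implemented here combines two cheap, fully
deterministic ingredients: a low-level binary segmentation of the footprint
and a fixed anatomical proportion rule applied to the resulting contours.

## Pipeline

### Segmentation backends

Three interchangeable backends produce a binary map from the grayscale
image; all are implemented from first principles in this package.

* **Thresholding.** Global strict thresholding (`dst = 255` iff
  `src > thresh`, default 127), Otsu's threshold (maximizing between-class
  variance over the 256-bin histogram, ties resolved toward the smaller
  threshold, binarization again by strict `>`), and adaptive-mean
  thresholding (local block mean minus an offset `C`, reflect padding).
* **Region split-and-merge.** A quadtree splits the image (padded with
  zeros to the next power-of-two square, then cropped back) until every
  block's intensity range is at most `tol` (default 16) or the block side
  reaches `minRegion` (default 4). Neighbouring regions (4-adjacency) merge
  while the range of their union stays within `tol`; the scan restarts
  after every merge. Because a region's range only grows, that restart
  policy is equivalent to always merging the lexicographically first
  eligible pair of region ids, which is how the kernel implements it —
  deterministically. A pixel is foreground when its final region's **mean**
  intensity lies strictly inside `(minThresh, maxThresh)`, default
  `(50, 100)`. The choice of the range statistic for homogeneity and of the
  region mean for the final window are interpretations: the classical
  formulation leaves both open, and these are the simplest
  order-independent, testable choices.
* **Canny.** The five classical stages, with 3×3 Sobel gradients and
  unnormalized L2 magnitude, so an ideal full-height step reaches a
  magnitude of several hundred — which is what makes double thresholds
  like `(300, 600)` meaningful on 8-bit data. Non-maximum suppression
  quantizes the gradient direction to four bins and compares against the
  two nearest neighbours without interpolation (ties kept, so a perfectly
  symmetric step may retain a 2-px line); hysteresis keeps weak pixels only
  when 8-connected to a strong pixel. Smoothing uses a 5-tap Gaussian with
  σ = 0.8 by default: a 5-tap kernel then covers ±3σ, and the straight-step
  response caps at ≈ 2.9 × step height, so a (300, 600) preset can actually
  fire strong seeds on realistic contrasts. (With σ = 1.4 on the same
  5 taps the cap is ≈ 2.2 × 255 ≈ 560, and no straight edge could ever be
  strong at 600.) All filtering uses symmetric reflect padding, so image
  borders generate no spurious edges.

### Contours, filtering, foot assignment

Border following (Moore tracing with Jacob's stopping criterion, the
Suzuki–Abe tradition: 8-connected foreground, outer borders only, holes
ignored) converts the binary map into ordered closed pixel contours. Each
contour's area is the absolute shoelace sum halved; contours with area
strictly above `minArea` (default 6000 px²) survive. This single filter is
also the toe-exclusion mechanism: toe blobs are an order of magnitude
smaller than a sole. Contour points sit on pixel centres, so the shoelace
area underestimates the filled pixel count by up to about half the
perimeter — the tests against a rasterization oracle use exactly that
tolerance.

Each surviving contour's bounding box goes to the left foot iff its
top-left `x < imgWidth/2` (strictly), else to the right — the literal
published rule, applied per contour so that a high-arch foot whose
forefoot and heel disconnect contributes two boxes that are later united.
A contour straddling the midline is assigned left and flagged.

### Geometric partition

For one foot, the union of its filtered contour points gives the foot
length `L = max(y) − min(y) + 1` (toes excluded by the area filter). `L` is
split top-down into bands of 30 % (forefoot), 30 % (arch) and 40 % (heel).
The published proportions rarely give integers; the package floors the
forefoot and arch bands and assigns the remainder to the heel — the largest
band absorbs the rounding and the three bands always sum to `L` exactly
(tested exhaustively for `L` in 3…2000). Each band's rectangle spans the
min/max x of the contour points falling in that band (the only geometry
available per band). The forefoot splits at
`foreMin + floor((foreMax − foreMin)/2)`; both halves share the split
column. The published construction is for the left foot, where the low-x
half is lateral (outer); the right foot mirrors both the inner/outer
assignment and the split rule (`foreMax − floor(span/2)`), so a mirrored
point set yields exactly the mirrored partition — a property the test suite
exercises on random fixtures.

Two further interpretation points: the published recipe spells one region
list entry "ourerFore", read here as `outerForefoot`; and foot length is
computed from whatever contours survive the area filter, so complete feet
with unusually large toe blobs would include them — with the default
`minArea` this does not occur in any generated morphology.

### Arch index

`archIndex()` classifies the toe-excluded footprint by the share of its
pixels in the middle y-third: high arch ≤ 0.21 < normal < 0.26 ≤ flat. It
is an area ratio, so it should be fed filled footprint pixels (the pipeline
option `archIndexFill` thresholds the original image inside the detected
foot's extent), not contour outlines.

### Evaluation protocol

Boxes are scored by exact pixel-count IoU under the half-open rectangle
convention, banded as poor (< 0.6), good ([0.6, 0.90)) and excellent
(≥ 0.90). The partitioner is a single-proposal detector — exactly one box
per region per foot — so average precision reduces to a sweep over IoU
thresholds; the default grid is 0.50 to 0.95 in steps of 0.05, and a single
threshold can be supplied for AP@0.5. Which protocol produced a published
mAP is generally not recoverable from a paper's text, so the report records
its grid in the `protocol` slot rather than guessing silently. Aggregation
is two-step: means within the normal and abnormal groups first, then the
unweighted mean of the two group means; pooled per-image means are also
reported for transparency. A ground-truth cell with no prediction counts as
a miss (IoU 0, a false negative) and is listed in `failures`.

## The synthetic benchmark

The generator replaces a private clinical dataset, so it is worth being
precise about what it does and does not emulate.

**Geometry.** A sole outline is drawn from two natural splines (lateral and
medial half-width profiles over the normalized foot axis), with per-type
modifications: an arch cut controlled by the midfoot contact fraction
(defaults 0.5 normal, 0.9 low arch, 0.1 high arch — matching "about half",
"near-complete" and "minimal" midfoot contact), a laterally/medially
deviated heel for the tilt types, and toe blobs (the inward tilt drops the
hallux; the outward tilt keeps only the hallux). Completeness levels:
`complete`, `missing_toes`, and `incomplete` (a random band of the sole
erased); incomplete samples whose true geometry can no longer be
partitioned carry no ground truth and are excluded from benchmark scoring.

**Pressure field.** Intensity follows the Euclidean distance transform of
the true geometry: a low-but-sharp contact plateau (~122 with the sensor
baseline) at the margins that climbs through the global threshold level 127
a few pixels inside, rising toward 255 in the pad cores, with high-contact
rims at the toe end and heel cap where real feet press hardest. Noise is
drawn on the 120×120 acquisition grid, bilinearly upsampled (so it is
spatially correlated at the sensor pitch) and scaled by the local signal —
piezoresistive cells fluctuate in proportion to load, and unloaded cells
read near zero. Defaults (noise sd 8 on the grid, 700×700 images, foot
length ~54–63 % of image height) were fixed once, during design, so that
the three published parameter presets reproduce their reported qualitative
behaviour: Canny (300, 600) traces exactly one closed outer ring per foot,
thresholding at 127 keeps the sole but erodes its low-pressure margins by a
few jagged pixels, and toe blobs stay below the area filter.

**Ground truth** applies the partition rule to the true noise-free sole
pixels. Scores therefore measure the pipeline's recovery of known geometry
through noise and segmentation — not agreement about how regions should be
defined.

**What is not emulated.** Real scans have a broad low-pressure penumbra
(partial sensor coverage, soft-tissue spread), pathological pressure
asymmetries, calluses and load hot-spots, and motion artefacts. Two
consequences matter. First, the split-and-merge variant with its published
(50, 100) mean window depends on exactly that penumbra; on the surrogate's
sharp-edged fields only mixed boundary blocks land in the window, they
rarely form a closed ring, and the variant scores near zero rather than the
mid-range values reachable on real data. Its relative ordering — clearly
below the Canny hybrid — is preserved; its absolute level is not
meaningful here. Second, all backends face easier boundary-localization
conditions than on clinical data, so absolute IoU levels on the surrogate
overstate what real scans would yield; the benchmark's value is the
*comparison* between backends and the end-to-end verification of every
published constant, not the headline number.

## Numerical and interface conventions

* Coordinates are 0-based, origin top-left, x = column, y = row;
  rectangles are half-open `[x, x+w) × [y, y+h)`, so areas are exact pixel
  counts and `bottomRight = (x+w, y+h)`.
* All strict/non-strict boundaries follow the published formulas exactly:
  `> thresh`, `> minArea`, `x < imgWidth/2`, open `(minThresh, maxThresh)`,
  band boundaries 0.6 and 0.90 inclusive on the upper band.
* YOLO annotations quantize normalized coordinates at 6 decimals, which
  round-trips integer-pixel boxes exactly on images up to ~10⁵ px.
* Determinism: fixed config + fixed inputs give byte-identical outputs;
  the generator threads one seed through every stochastic draw and records
  per-sample seeds in the manifest.
* Degenerate inputs fail loudly and specifically: constant images for
  Otsu, feet shorter than 3 px or with an empty band, boxes out of bounds,
  unknown class ids.

## Problem sizes

The shipped test suite regenerates everything from code: unit fixtures up
to 64×64, oracle sweeps (100 random polygons against a Pick's-theorem and
rasterization oracle, 50 random blob masks against a boundary-pixel
oracle, 1000 random box pairs against pixel-count IoU, exhaustive Otsu),
and a 200-image 700×700 benchmark at the published dataset composition
(80/30/30/30/30) for the backend comparison. The full suite runs in a few
minutes on one CPU; `scripts/acceptance.R` re-runs the benchmark alone.

## Limitations

Static composite images only (no gait sequences); axis-aligned boxes, not
free-form masks, matching the bounding-box annotation modality; no
heel-tilt classification from geometry; pediatric and severely fragmented
footprints out of scope. The generator is a geometric surrogate: passing
its benchmark demonstrates correct and robust implementation of the
method, not clinical performance.
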