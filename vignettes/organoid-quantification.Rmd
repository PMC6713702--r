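---
title: "Tiled organoid quantification: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiled organoid quantification: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgadetect)
```

This vignette is the package's account of what it computes and why the
pieces are shaped the way they are. The package quantifies spherical
organoids in large brightfield images by sliding-window detection,
cross-tile aggregation, and ellipse morphometry, and ships the dataset-side
tools (annotation schema, annotator consensus, evaluation metric) plus a
synthetic scene generator that makes every stage testable without any
trained model or external data.

## Coordinate conventions

All boxes are axis-aligned pixel rectangles in **0-based, half-open**
coordinates with the origin at the image's top-left corner: a box covers
pixel columns `[xmin, xmax)` and rows `[ymin, ymax)`. The annotation CSV
format this package reads and writes states only that the origin is the
top-left corner; whether its `xmax`/`ymax` are inclusive is not specified
anywhere, so the half-open reading is a package decision, chosen because it
makes widths exactly `xmax - xmin`, makes areas additive, and matches how
array slicing composes. IoU is computed on these half-open areas, which is
identical to counting member pixels of the rasterized boxes (the test suite
verifies this equivalence exactly on random boxes).

Images follow the EBImage layout: `dim[1]` is width (x), `dim[2]` height
(y).

## Tiling

`plan_tile_grid(width, height, patch_size, overlap)` covers the frame with
the minimal integer grid of square windows: with `stride = patch_size -
overlap`, the window count per axis is the smallest `n` with
`(n-1)*stride + patch_size >= extent`, and the frame is zero-padded (black)
at the bottom and right up to `(n-1)*stride + patch_size`. Defaults are a
450 px window with 50% overlap. 450 px is one of the two patch sizes the
annotation workflow used; 50% overlap guarantees that any object smaller
than the stride lies fully interior to at least one window, which is what
makes the edge-rejection rule below lossless.

## Edge rejection and aggregation

Detections whose box comes within `edge_margin` pixels (default 2) of a
window side are discarded, because the object may be truncated by the
window. Two deliberate refinements:

* **Border exception.** If the window side coincides with the boundary of
  the original (unpadded) image, boxes near it are kept. Without this
  exception an organoid touching the image perimeter could never be
  reported by any window.
* **Margin semantics.** "Near" means distance strictly below the margin,
  so `edge_margin = 0` disables the filter. The 2 px default tolerates
  detectors that clamp their boxes to the patch frame.

Surviving boxes are offset by their tile origin, clipped to the unpadded
frame (boxes wholly inside the padding strip are dropped), and merged by
greedy non-maximum suppression (NMS): detections are visited in descending
score order, ties broken by lexicographic box coordinates for cross-platform
determinism, and one is kept iff its IoU with every kept detection is below
`merge_iou_threshold` (default 0.5). NMS was chosen over box fusion or
coordinate averaging because it is idempotent and preserves the coordinates
the detector actually produced; the aggregation procedure itself was an
open design point. A consequence worth stating plainly: **two genuinely
distinct objects whose true boxes overlap at or above the merge threshold
cannot both survive NMS.** This is a property of the aggregation rule, not
a bug; the exact-recovery studies in the test suite therefore use scenes
with disjoint ground-truth boxes, and on real crowded cultures the merge
threshold trades duplicate suppression against merging genuinely
overlapping neighbours.

## Detector backends

The per-patch detector is a plug-in: any `f(patch, origin)` returning
tile-local boxes with scores in `[0, 1]`, deterministic for a fixed patch.
Three backends ship with the package:

* `make_oracle_detector(gt)` returns the known ground truth clipped to each
  tile — the testing backend that isolates the tiling/aggregation logic
  from detection quality.
* `make_reference_detector(config)` is a classical band-pass blob detector:
  on the inverted patch, the response `smooth(sigma_fine) -
  smooth(sigma_coarse)` is thresholded (Otsu by default), closed and
  hole-filled, labelled into components, filtered by area and by an
  in-focus criterion (mean gradient magnitude of the original patch along
  the component boundary, default threshold 0.02 intensity units/px —
  chosen from the clear separation between sharp and strongly defocused
  rims in the synthetic fixtures), and each surviving component is reported
  with a tight box. The box is taken from the component re-thresholded at
  half its peak response, which removes the systematic dilation (about
  `sigma_fine`) that the fine smoothing adds to the Otsu mask — a standard
  half-max criterion, not a tuned constant. Defaults (`sigma` 2/15 px,
  `min_area` 150 px², `score_floor` 0.2) are matched to the synthetic
  generator's default organoid radii of 15–60 px. They are fixture-scale
  settings, **not** claims about real microscope data; the reference
  detector exists so the pipeline is testable at desk scale, while a
  trained neural detector is expected to be attached through
  `make_adapter_detector()` (patch out as 8-bit PNG, detections back as
  CSV) for real images.

## Morphometry

Each final box is interpreted as the bounding box of an ellipse inscribed
in it, the only construction whose axis lengths equal the box sides. With
pixel size `s` µm/px: `major = max(w, h) * s`, `minor = min(w, h) * s`,
`area = pi/4 * w * h * s^2`. The physical scale comes from user
configuration; reading scale bars off the image is out of scope. Reported
quantities are in µm and µm².

## Evaluation metric

`per_image_precision(gt, pred)` is the fraction of ground-truth boxes
matched by a prediction at IoU ≥ 0.7, and `mean_average_precision()` is its
mean over images. Three consequences, all deliberate and all asserted by
tests:

* The metric is a **recall**: false positives never change it.
* Duplicate predictions count once (matching is one-to-one).
* Images with zero ground-truth boxes are excluded from the mean — their
  per-image value is undefined (0/0); the alternative (scoring them 1 or 0)
  would bias the mean by prevalence of empty images.

Greedy matching is provably optimal here: at any IoU threshold above 0.5,
two disjoint ground-truth boxes cannot both overlap one predicted box at or
above the threshold (their intersections with it would be disjoint and each
would need more than half its area), so the match graph has degree ≤ 1 on
both sides and the matching is unique. The test suite additionally verifies
greedy-vs-exhaustive equality on small instances at thresholds down to 0.3.
A VOC/COCO-style AP over score sweeps is deliberately not implemented; this
package reproduces the per-image-fraction definition.

## Annotator consensus

`pairwise_agreement` greedy-matches two workers' box sets at IoU ≥ 0.7 (the
same match rule the evaluation uses, since no separate value is documented
for annotation) and returns the Dice-style ratio `2|M| / (|a| + |b|)`,
defined as 1 when both sets are empty. The crowdsourcing platform that
originally computed agreement never published its formula, so this is a
package decision. Escalation to a third worker triggers strictly below 0.8.
Final aggregation clusters boxes across workers by greedy cross-worker
matching (globally, in descending IoU order, ties broken by worker id then
box index, workers sorted by id first so the result is independent of input
order; no worker contributes twice to one cluster), scores each cluster by
the fraction of workers contributing, keeps clusters at support ≥ 0.7, and
reports the rounded coordinate-wise mean box. A consequential reading: with
three workers, a box drawn by only two has support 0.667 < 0.7 and is
dropped. The alternative reading ("70% agreement" as mean IoU) is possible
but unsupported by any published formula; the support reading is
implemented because it extends the two-worker case coherently.

## The synthetic scene generator

`generate_scene()` renders organoids as rotated ellipses with a dark rim
and lighter lumen on a bright background — the appearance of brightfield
organoids at low magnification — and reproduces the artifact taxonomy that
defeats classical segmentation: optional overlap, a defocused fraction
(per-organoid Gaussian blur), heterogeneous sizes (uniform semi-major axis
in 15–60 px by default, minor/major ratio 0.7–1 for near-spherical
morphologies), a linear illumination gradient (default 20% peak-to-peak),
additive Gaussian noise (default sd 0.02), and arbitrary density. The
ground-truth box is the tight bound of the rendered pre-blur pixel set, so
ground truth is exact by construction. All randomness comes from one stream
seeded per scene, drawn in a documented order, so scenes are reproducible
across platforms at integer-box precision.

What the generator does **not** emulate: crypt-like or budding (non-convex)
morphologies, texture inside the lumen, optical halo/diffraction effects,
debris and bubbles, and the correlated focus structure of a 3D droplet
(defocus here is independent per organoid). Passing tests on synthetic
scenes therefore demonstrate the correctness of the tiling, filtering,
aggregation, measurement, consensus and evaluation logic — not the accuracy
of the reference detector on real cultures, which is exactly why the
detector is pluggable.

## Problem sizes and numerical choices in the test suite

The end-to-end studies run at sizes chosen to exercise multi-tile grids
while keeping the suite quick: 20 seeded full-frame scenes (1500 × 1125,
5–60 organoids, disjoint placement) for lossless oracle recovery, and 20
seeded easy scenes (600 × 450, 6 in-focus non-overlapping organoids, mild
gradient and noise) for reference-detector recovery, where the suite
requires mAP ≥ 0.9 and mean absolute major-axis error ≤ 10% against the
true rendered axes. The axis comparison uses `2 * semi_major` as truth;
note the axis-aligned box of a rotated ellipse underestimates `2a` by up to
~14% at 45° for ratio 0.7, so part of the observed error budget is geometry
rather than detection. Degenerate inputs error early and loudly: boxes with
non-positive extent, clipping that empties a box (unless dropping is
requested), overlap ≥ patch size, non-finite pixels, impossible non-overlap
placements (bounded rejection sampling, default 1000 tries per organoid).
Scenes are quantized to the 8-bit grid in code before writing, so files
round-trip bit-exactly through both PNG and TIFF writers.

## Known limitations

* The recall-style metric says nothing about false positives; a detector
  that boxes everything scores 1. Use it as designed — to compare against
  manual annotation coverage — not as a standalone quality measure.
* NMS-based aggregation cannot report two true objects overlapping at or
  above the merge threshold (see above).
* Morphometry assumes the axis-aligned inscribed ellipse; elongated
  organoids at 45° are measured along the box diagonal's sides, not their
  true principal axes.
* The reference detector handles spherical morphologies only, and its
  defaults target the synthetic fixtures' scale.
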