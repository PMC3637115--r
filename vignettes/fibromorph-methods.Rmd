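---
title: "Methods: morphometry and motility of cultured fibroblasts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometry and motility of cultured fibroblasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibromorph)
```

## Scope and model

fibromorph quantifies two things about cultured duodenal fibroblasts:
the *geometry* of their intracellular fluorescence signals (collagen
types I/IV, TG2) on still images, and the *motility* of their nuclei
over a 72-hour time-lapse recording. Both are group-level analyses:
per-object or per-cell measurements are summarized as mean ± SD per
group (e.g. celiac vs control) and compared by one-way ANOVA with
significance at p < 0.05, with no multiple-testing correction (each
parameter is reported as its own comparison; this is flagged here so
downstream users can correct if they compare many parameters).

The analysis assumes single-channel 8-bit images (0–255 intensity
levels) with a known physical pixel size. The calibration is mandatory
configuration and never inferred from image files: μm-scale morphometry
is meaningless without it and stored files routinely lack trustworthy
metadata.

## Segmentation

**Thresholding.** The automated threshold maximizes the between-class
variance of the 256-bin intensity histogram (Otsu's criterion). The
method is deterministic: ties resolve to the lowest level, and pixels
*equal* to the threshold are background (foreground is strictly above),
so dim diffuse signal is cut off rather than absorbed. A constant image
raises an error — there is no two-class structure to find.

Plain Otsu always produces *a* split, even on an image of pure
background noise, where the two "classes" are the lower and upper
halves of the noise distribution. Thresholding such an image would turn
noise into large percolating foreground components. `auto_threshold()`
therefore checks the contrast of the split: if the class means are
separated by fewer than `min_separation` (default 4) pooled
within-class standard deviations, the image is reported as signal-free
and the mask is empty. Genuine fluorescent objects sit tens of noise
SDs above background, so the guard does not affect images with signal.
The default of 4 sits between the ~2.7-SD separation that a pure
Gaussian noise split produces and the weakest plausible real signal
(a peak of ~30 over a background of 10 ± 3 still separates by ~7 SD).

**Nucleus frames.** Nuclei occupy a tiny fraction (≲0.5%) of a
time-lapse frame, and a global Otsu split can lock onto the background
noise because the bright class carries almost no histogram weight. When
the split fails the separation check, `detect_nuclei()` re-runs Otsu on
the pixels above the current level, recursively (multi-level Otsu, at
most 8 levels), until a well-separated bright class emerges. This keeps
the thresholding rule identical everywhere — only its starting
population changes.

**Object detection.** Foreground objects are 8-connected components
(the common default of ROI-counting tools), labeled in raster-scan
order so results are reproducible run to run. The minimum object size
is calibrated from measured areas of representative cells (canonically
twelve): `min_size = floor(0.5 × min(reference areas))`. The source
procedure specifies the calibration inputs but not the formula; half
the smallest reference cell is our interpretation — it guarantees every
reference cell clears the gate with margin while rejecting debris an
order of magnitude smaller. The factor is exposed as configuration.

## Morphometry

Each object's boundary is extracted as the sub-pixel marching-squares
iso-contour at level 0.5 (saddle cells resolved as connected
foreground, consistent with 8-connectivity).

**Feret diameters.** The feret (maximum caliper) diameter is computed
as the diameter of the convex hull of the boundary — for a convex
polygon the maximum caliper width equals the largest vertex-to-vertex
distance. The orthogonal diameter is the hull extent perpendicular to
the max-feret axis. The *circularity index* is their ratio F⊥/F. An
alternative reading (minimum feret / maximum feret) differs for concave
shapes; we use the perpendicular extent because that is what "the major
orthogonal diameters" describes, and the tests pin this choice.

Because the iso-contour runs half a pixel outside the outermost pixel
centres on every side, both calipers of a detected object are corrected
by one pixel; without the correction a digitized 50 μm ellipse measures
51 pixels across at 1 μm/px.

**Perimeter.** The raw marching-squares polygon overestimates the
perimeter of a digitized disk by 6–9% (staircase bias: the polygon
zig-zags along oblique edges). The package therefore smooths the closed
contour with a circular moving average (window 5 vertices) before
measuring length; residual error is below 1% on disks and ellipses and
about 1% on squares (corners are slightly cut). Window 5 is the
smallest window that removes the staircase; larger windows start to
erode genuine shape detail. The raw contour is retained as the object
boundary. Area is simply pixel count × pixel size², which is accurate
to well under 1% for objects tens of pixels across.

**Complexity.** perimeter/area (1/μm). Exactly 2/r for a disk, which
the test suite uses as a closed-form check.

## Motility

Frames are captured every 10 minutes for 72 h (433 frames) but tracking
uses only the frames sampled every 12 h, mirroring manual nucleus
tracking at fixed waypoints; the full-cadence stream exists for fixture
realism. The sampling interval must be a multiple of the cadence *and*
divide the recording, so the final frame is always sampled and
"complete" tracks genuinely span the recording.

Nucleus detections at consecutive sampled timepoints are linked
greedily: candidate pairs within the gate (default 100 μm per 12 h,
about three times the largest plausible mean 12-h step) are accepted in
order of increasing distance, ties broken by lower track id then lower
detection index. Tracks that miss a match terminate; only tracks
spanning every timepoint are returned, matching the study design of
following a fixed set of cells for the full 72 h. How cells lost to the
field were handled in the original workflow is not stated;
complete-track filtering is our decision and is reported openly by the
tracker (incomplete tracks are simply absent).

Per cell, *total displacement* is the path length over the 12-h
waypoints — not the net start-to-end vector, which is also reported as
a secondary quantity — and *velocity* is total displacement divided by
elapsed time, averaged per cell first (mean of per-cell ratios).

A blob much larger than the typical blob in its frame (>1.4×; two equal
nuclei fused at under two radii of separation cover ≈1.5× the single
area) is flagged as a likely merger with a warning.

## The synthetic-data generator

The generator is the package's validation instrument: it produces
inputs whose true answers are known exactly.

**Still scenes.** Each cell is a `shape_spec`: geometry class, target
feret, target circularity, centre, orientation, peak intensity. Signet
(rounded, celiac-like) cells render as superellipses with exponent 2.5
whose semi-axes are recalibrated numerically so the *realized* feret
and circularity equal their targets (a raw exponent-2.5 superellipse
bulges ~7% past its semi-axis along the diagonal). Spindle
(elongated/Y-like, control-like) cells render as a bipolar body with a
polynomially tapering half-width profile plus, by default, a third
short arm — the Y-shape of a migration-ready fibroblast; the two tips
sit exactly one target-feret apart and the transverse extent equals
circularity × feret, so realized indices match targets by construction,
up to pixelation. The class boundary (circularity 0.45) is enforced at
spec construction. Scenes place objects on a truncated-Gaussian noise
background (default 10 ± 3) with uniform object intensity at the spec's
peak plus mild texture; overlapping footprints are an error because the
detection model assumes discrete objects. Defaults: 764 × 560 px
(stored-image matrix of the source workflow), 0.5 μm/px, so 30–60 μm
cells span realistic pixel counts.

**Time-lapse.** Nuclei follow a persistent random walk: one step per
12-h segment with truncated-normal length (lower bound 0), direction
correlated with the previous segment (`persistence`, default 0.3 — a
moderate directional memory typical of fibroblasts; persistence 1 gives
straight lines), positions interpolated linearly to the 10-min frame
cadence and reflected at the field borders. Over a 72-h recording the
expected true path length is 6 × `step_mean`, which makes the generator
exactly calibratable to published displacement statistics (truncation
at zero inflates the mean by <1% at the parameter sets used). Frames
render on demand (background noise plus one Gaussian blob per nucleus,
radius 5 μm), each from its own derived seed, so long sequences stay
cheap and bit-reproducible.

The time-lapse default calibration is 1.0 μm/px on the 764 × 560 grid
(a 764 × 560 μm field): time-lapse acquisition at 10× samples much more
coarsely than the high-power stills, and the field must hold 72-h
trajectories. Start positions are inset 150 μm from the borders and at
least ~90 μm apart (density-permitting), keeping border reflections and
cell–cell encounters rare.

**What the generator does not emulate:** point-spread functions,
photobleaching, z-structure, multi-channel composites, intensity
texture of real staining, cell division, or shape change during
migration. Passing tests therefore demonstrate that the *measurement
chain* is correct and calibrated, not that it is robust to every
artifact of real microscopy — JPEG inputs, for instance, are accepted
but flagged, because lossy compression perturbs boundaries.

**Validation-study sizes.** The test suite and the acceptance script
use: 100 random spec pairs for spindle/signet separation; 500 cells for
the path-length calibration; 20 five-cell sequences for tracker
identity accuracy; 10–12 five-cell sequences per motility regime for
displacement recovery; 1000–2000 replicates for the ANOVA power and
type-I-error simulations. Five cells per field matches the density of
the emulated study, which followed five cells in each of three movies
per group; at three times that density, greedy linking begins to swap
identities when trajectories cross (nearest-distance assignment
systematically shortens crossed paths), which is a property of the
linking rule, not of the cells.

## Statistics

`summarize()` reports mean, sample SD (n−1; the convention for
biological replicates), n, median and range. `anova_oneway()` is the
classical fixed-effects F test (for two groups F = t² of the
pooled-variance t test, which the suite verifies to 1e-9); the
degenerate all-values-identical case is defined as F = 0, p = 1 rather
than an error, and distinct means with zero within-group variance as
p = 0. `power_simulation()` draws groups from truncated normal laws —
truncation bounds express physical validity (circularity in (0, 1],
areas positive) and distort the published means/SDs negligibly — and
reports the rejection rate and median p. TG-activity normalization is
blank-corrected OD per 10⁴ cells; the 10⁴ is a readability convention
with no effect on fold changes.

## Known limitations

* Global thresholding only; no illumination-field correction beyond
  what Otsu absorbs. Strong shading across a field will bias object
  footprints.
* The tracker has no model of division, entry/exit, or occlusion
  beyond complete-track filtering, and distance-greedy linking is
  known to shorten paths when trajectories cross (see above).
* The circularity of very small objects (feret near the 8-px rendering
  floor) carries half-pixel quantization of order several percent.
* The exact thresholding variant and ROI tool of the emulated workflow
  are not documented; Otsu is a reasoned choice, and all downstream
  contracts are pinned to it.
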