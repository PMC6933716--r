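---
title: "Methods: voxel-based panicle phenotyping from multi-view imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-based panicle phenotyping from multi-view imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(panicler)
```

This vignette explains the models, numerical conventions and design
choices behind `panicler`, and what the synthetic-data generators do and
do not emulate.

## The measurement problem

A developing rice panicle gains seed volume (grain filling) and shifts
from green to yellow (maturation) over the weeks after fertilization.
Both dynamics predict final yield but are classically measured
destructively. The pipeline implemented here derives them
non-destructively from weekly multi-view imaging sessions: 120 RGB views
per session from two cameras rotating around the hanging panicle, an
external multi-view-stereo (MVS) reconstruction of a colored point cloud
per session, and the trait extraction below. The package consumes the MVS
output (PLY); it does not perform reconstruction itself.

## Pre-processing

Images are converted to HSV and thresholded with closed intervals; the
chamber default (hue 0–1, saturation 0–1, value 0.15–1) reduces to
retaining pixels with value ≥ 0.15, which removes the black walls and
board under the chamber's constant illumination. Intervals are closed on
both ends: a pixel at exactly 0.15 is kept. Residual bright specks are
removed as 8-connected components smaller than `min_component_px`
(default 50 px). The per-image fraction of foreground removed at this
step is reported so users can verify on their own data that denoising is
a sub-percent correction; the operator itself (area opening by connected
components) is a choice — only the effect of the original denoising step
is documented, not its mechanism.

## Scene segmentation and alignment

MVS output has arbitrary scale, orientation and origin, so traits are
only comparable after mapping every cloud into one canonical chamber
frame. The constant reference geometry makes this possible: a board
surface with a central aperture (canonically the plane $z = 0$ with the
aperture center at the origin) and three checkerboard walls descending
below it. The fourth side is the camera opening.

Plane recovery is deterministic given the cloud: the cloud is decimated
on a coarse voxel grid (pitch = scene diagonal / 150) so that a densely
sampled panicle cannot out-vote the two-dimensional wall surfaces; a
seeded sequential RANSAC extracts up to six dominant planes (600
candidate triples per plane, total-least-squares refinement with
iterated MAD outlier rejection — one pass is not enough because points
dragged in from adjacent walls at the chamber edges bias the fit); and a
consistency search picks the chamber set: a parallel pair (side walls)
plus two planes orthogonal to the pair and to each other. The board and
the back wall are told apart by the aspect ratio of their in-plane point
extents, which is why the chamber model requires the three rectangle
aspect ratios to be pairwise distinct — identification then needs no
markers. Orientation is fixed by which side of each plane the interior
points lie on, and the scale comes from the side-wall separation, whose
canonical width is known.

Landmarks are then constructed from plane intersections (the two lower
back corners, their counterparts at the wall top, and the aperture
center) and a least-squares similarity fit (Umeyama) maps them onto
their canonical positions; the residual RMS is attached to the returned
transform. On noiseless synthetic scenes the recovered transform composes
with the generating one to identity at machine precision; the package's
tests require 1e-6.

Component labels: points within `wall_distance_tol` (1 cm, scaled into
data units) of a selected plane are checkerboard; of the rest, gray
points (8-bit channel spread ≤ 30) in the top decile of the scene height
are the hanging hook/apparatus; the remainder is panicle. All three
tolerances are exposed in the chamber model.

## Voxelization and traits

The same bounding cube, fixed in the canonical frame, encloses every
aligned cloud; each edge is divided into `resolution` bins (default
1000). Binning is half-open with floor indexing — voxel
$\lfloor (p - c_{\min})/h \rfloor$ — and coordinates exactly on the
maximum face are clamped into the last voxel; this is the only
convention that makes the bins disjoint and exhaustive. A voxel is
filled if at least one panicle point maps to it, and it carries the
arithmetic mean RGB of its member points. Points outside the cube raise
an error rather than being clipped: after correct alignment the panicle
lies inside the cube, so an out-of-bounds point signals a failed
alignment.

Traits: `voxel_count` (filled voxels; volume proxy), per-channel sums of
voxel mean colors (8-bit units throughout, for determinism and
cross-session comparability), and `rg_ratio`, the ratio of the red to the
green channel *sums* — not the mean of per-voxel ratios. A zero green sum
makes the ratio undefined; the low-level extractor raises a classed error
and the session pipeline flags `NA` instead of propagating infinity.

## The 2D comparison method

Color segmentation keeps the panicle but also the checkerboard's green
squares, so square-like regions must be removed by shape. Solidity is
region area over the area of its convex image (pixels whose centers fall
inside the convex hull of the region's pixel centers — this keeps
solidity ≤ 1 and makes a filled square exactly 1). Eccentricity comes
from the ellipse with the same second central moments as the pixel set
(eigenvalues $\lambda_1 \ge \lambda_2$ of the coordinate covariance plus
the 1/12 pixel term; $e = \sqrt{1 - \lambda_2/\lambda_1}$); axis lengths
use the uniform-ellipse convention $4\sqrt{\lambda}$.

A region is excluded iff (solidity > 0.7 AND eccentricity < 0.95) or
area < 1000 px. The AND combination is a deliberate reading of an
ambiguous rule: a region must look both compact and round to be a
square. Individual panicle fragments can exceed 0.7 solidity, and an OR
rule would delete them; OR remains available behind
`exclusion_mode = "or"`. Labeling is 8-connected so thin diagonal branch
segments stay in one region.

## Seed-scan morphometry

Scans are segmented with hue 0–0.3, saturation 0.2–1, value 0.5–1
(closed intervals; yellow seeds pass, the black background and bluish or
washed-out pixels fail). Morphological opening with a disk of radius 2 px
(default) removes branches thinner than twice the radius and disconnects
the seeds; regions with minor axis < 8 px or area < 30 px are residue
and dropped. The numeric values of the opening radius and the "too thin"
rule are this package's defaults, exposed in the configuration, since
only the operations themselves are fixed by the method. Projected
surface area is measured *before* opening: deleted branch pixels are
part of the panicle's projected area even though they are not seeds.
This pre-/post-opening choice was genuinely open; pre-opening is used
and documented.

## Statistics

Pearson matrices use pairwise-complete observations; p-values come from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df, the classical transform.
Constant traits leave r undefined and are flagged rather than propagated
as NaN. No multiple-testing correction is applied by default (matching
the raw-p convention of the weekly-imaging analyses this package
supports); Benjamini–Hochberg is available by flag. Group comparisons
use classical equal-variance Student's t (Welch by flag) at α = 0.1 and
a compact letter display built by insert-and-absorb over the pairwise
significance matrix. Trajectory clustering defaults to Euclidean
distance with Ward linkage — standard for magnitude-plus-shape
clustering of growth trajectories — with both choices configurable; the
tree is cut at k = 4 by default.

## Synthetic data: what it emulates, and what it does not

The generators produce every input format the pipeline reads, with
ground truth attached: chamber scenes (volumetrically sampled
ellipsoidal seeds on drooping branches plus a thin rachis, checkerboard
walls, gray hook), orthographic multi-view masks with optional
checkerboard-square distractors, seed scans (non-overlapping ovals on a
jittered grid joined by thin connectors), and a full cohort in the
55-plant study design (11 genotypes × 2 treatments × alternating 2–3
replicates).

Key design decisions, chosen once:

- **Deterministic skeleton.** Branch angles and seed centers are fixed
  given the counts (`placement_jitter = 0` by default). Seeds then grow
  concentrically with the weekly volume multiplier, so the true occupied
  volume is a strictly increasing function of that multiplier and rank
  statistics against it are structurally exact. Randomized architectures
  are available by setting `placement_jitter > 0`.
- **Growth design.** Two growth groups with weekly volume schedules
  (1, 1.3, 4.5) — sustained late filling — and (1.7, 2.6, 3.4) — early
  vigor. All six group-week factors are pairwise separated by ≥ 1.25×
  and within-group genotype sizes span 0.93–1.07, so every scene's
  volume sits in its own band; the two trajectory shapes differ enough
  (≈ 22° between their direction vectors) for Ward clustering to recover
  the groups exactly.
- **Maturation.** Point colors interpolate green (50, 160, 60) → yellow
  (210, 180, 60); R:G of the mixture is strictly increasing in the
  stage. Control weeks use stages (0.15, 0.45, 0.75) and the
  high-night-temperature treatment (0.30, 0.60, 0.90), encoding
  accelerated maturation at equal geometry.
- **Sampling density.** Cohort scenes sample seeds at 2500 points/cm³ so
  that occupancy at the demonstration resolution (200³ over a 24 cm
  cube, i.e. 1.2 mm voxels, ≈ 4.3 points per voxel) is saturated and
  voxel count tracks volume rather than point count. Standalone scene
  examples default to 150 points/cm³, which is deliberately unsaturated
  — there voxel count tracks the point budget, as sparse MVS clouds do.
- **True volume** is the rasterized union of the seed ellipsoids (grid
  of 300³ cells over the panicle's bounding box), so seed overlap is
  handled exactly at grid precision. The thin rachis is excluded from
  the truth volume on purpose: it contributes a constant occupancy
  offset, not seed volume.
- **End-points.** Seed number and weight are proportional to the final
  volume multiplier with Gaussian relative noise (`noise_sd`, default
  0.05); at zero noise replicates are exact copies and the voxel-weight
  correlation approaches 1 up to discretization.

What the generators do **not** emulate: MVS reconstruction noise and
holes, camera calibration error, perspective (views are orthographic),
illumination gradients, overlapping seeds on the scanner glass, and
fertile/sterile seed classification. Passing tests on synthetic data
therefore validate the geometry, binning, filtering and statistics of
the pipeline — not robustness to reconstruction artifacts of any
particular MVS tool.

## Problem sizes and numerical choices

The test-suite and acceptance runs use resolution 200 for full-pipeline
work and resolution ≤ 100 for oracle comparisons, with the 1000³ default
retained for production use; these sizes were chosen so a complete run
is a desk-scale computation. Voxel keys are packed as
`i + N(j + Nk)` in doubles, exact up to N = 1000 (10⁹ < 2⁵³). Plane
RANSAC uses a fixed internal seed, so chamber detection is a
deterministic function of the input cloud. Degenerate inputs are classed
errors: empty clouds cannot be segmented, collinear landmarks raise a
rank error, fewer than four detected planes an alignment error, points
outside the cube an out-of-bounds error, and a zero green sum an
undefined-ratio error.

## Known limitations

- Occupancy is a volume *proxy*: shell-only (hollow) reconstructions
  with different surface-to-volume characteristics between genotypes
  would bias comparisons; the package reports occupancy only.
- The chamber identification requires the three reference rectangles to
  have pairwise distinct aspect ratios and all four planes visible in
  the cloud.
- Absolute metric calibration (cm³ per voxel) is available only through
  the 1 cm checkerboard square edge and is exposed as metadata, not
  applied to traits.
- The compact letter display uses raw pairwise p-values by default; with
  many groups the family-wise error is uncontrolled unless `adjust =
  "BH"` is chosen.
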