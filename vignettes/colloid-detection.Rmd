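---
title: "Detecting colloids in micromodel image sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting colloids in micromodel image sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colloidspot)
```

## The detection problem

Pore-scale transport experiments image a transparent micromodel — a
microfluidic replica of a porous medium — while micrometre-scale colloids
are carried through it by flow. At a resolution of about 2.9 µm/px a
4.3 µm colloid spans 1–2 px, so each frame is a three-level scene: dark
solid grains, lighter fluorescent pore fluid, and bright near-point
colloids. Some colloids attach to grain surfaces and stay put; the rest
advect at the pore-water velocity (a few px per frame at 10 frames/s).
Detection is hard not because the colloids are faint but because they are
*small*: one bright pixel carries almost no shape information, so any
detector must lean on intensity, motion, scale, or a combination.

`colloidspot` implements eight detectors in four families and fuses the
best three by majority vote. This vignette records how each method works,
the parameters that matter, the design decisions taken where the
literature leaves choices open, and what the synthetic benchmark does and
does not establish.

## The detectors

**Intensity segmentation.** `kmeans_detect()` clusters the pixel
intensities (a one-dimensional feature: the images are grayscale) into
`k = 3` groups, one per scene region, and takes the highest-center cluster
as the colloid class. Lloyd iteration runs to a center-movement tolerance
of 1e-4 with at most 300 iterations, 10 random restarts keeping the lowest
within-cluster SSE, initial centers drawn uniformly without replacement
from the distinct intensity values, and an empty cluster re-seeded at the
point farthest from its center — all standard choices, fixed here because
the method itself does not prescribe them. Since the feature is 1-D and
8-bit, the implementation collapses the image to a 256-bin weighted
histogram, which is exact and makes the cost independent of image size.
`otsu_detect()` thresholds at the exhaustive maximizer of the inter-class
variance `P0·P1·(m0−m1)²` over all 256 thresholds; class 0 holds
intensities strictly below `T`, ties go to the smallest `T`, and the
foreground uses `>= T` so that intensities sitting exactly at the
threshold stay with the bright class.

**Motion.** `two_frame_diff()` and `three_frame_diff()` threshold absolute
frame differences (strict inequality); `mfd_detect()` averages the three
pairwise absolute differences of a frame triplet before thresholding; and
`fdbs_detect()` ANDs a two-frame difference with a difference against a
static background model, which suppresses the trailing ghost at a
particle's previous position. The background model is the per-pixel
temporal median of the sequence — the construction is not prescribed by
the methods themselves, and the median is the standard robust choice for a
fixed camera; no frame alignment is performed for the same reason. The
motion threshold defaults to `T = 25` on the 8-bit scale, comfortably
above sensor noise and far below the ~100-level colloid contrast; it is a
config knob (`motion_threshold`). Differences are taken as absolute values
throughout: signed 8-bit subtraction would wrap around and corrupt the
result, and absolute differences are what the two-frame definition uses.
Detectors that need a previous/next frame produce no output on boundary
frames rather than padding.

**Linear filters.** `laplacian_detect()` correlates with the 4-neighbour
stencil of the *negated* Laplacian (center +4, edge neighbours −1) so that
bright spots yield positive central responses — the sign convention is
ours, chosen to make "response > threshold" the detection rule; the
4-neighbour stencil matches the characteristic one-white-dot,
four-black-dots pattern of a point target. `dog_detect()` uses a
difference of two Gaussians (σ₁ = 0.5, σ₂ = 2 on a 3×3 support) as a
band-pass spot filter. Each truncated Gaussian is renormalized to unit sum
over the 3×3 support before subtraction: at this aggressive truncation the
continuous normalization would not integrate to one, and per-support
normalization guarantees an exactly zero-sum kernel, hence zero response
to any constant region. A pixel is detected when its response exceeds the
threshold *and* some 8-neighbour has a response of the opposite sign — the
zero-crossing condition; the conjunction is our operationalization of
"zero-crossing points with an extreme change in brightness". Response
thresholds default to 40 (Laplacian) and 10 (DoG) on 0–255 inputs; both
are exposed in the configuration. Convolution uses replicate-edge padding.

**Morphology.** Binary erosion/dilation follow the set definitions (probe
fits inside the foreground / reflected probe hits it), with out-of-bounds
treated as background; grayscale erosion/dilation are local min/max that
ignore out-of-bounds cells (the identity element of the reduction), so the
frame border creates no artificial top-hat response. Disk structuring
elements include every offset with `dr² + dc² ≤ r²`. `tophat_detect()`
computes the white top-hat (image minus opening, disk r = 2) and
binarizes it with Otsu; `dilation_detect()` dilates with disk r = 4 and
binarizes the result the same way. The post-binarization step is not part
of the classical operators; Otsu was chosen for parameter-freeness and can
be overridden with a fixed threshold (`post_threshold`).

**Object extraction.** Masks become detections via 8-connected components
(diagonal contact matters at 1–2 px scale), an area filter (defaults 1–200
px; the upper bound rejects pore-sized regions passing a global
threshold), and unweighted centroid computation. Coordinates are `(row,
col)`, 0-based, pixel centers at integers.

**Ensemble.** The vote is object-level: detections of the three methods
are greedily clustered — closest cross-method pair first, then the nearest
third-method detection within the vote radius of the cluster centroid —
and clusters supported by at least two methods are emitted as fused
detections (mean centroid, summed area). The default trio is top-hat, DoG
and *k*-means, the three strongest single methods; the vote radius is 5 px,
about twice the rendered colloid radius, small enough that distinct
colloids (kept ≥ 10 px apart by the generator) can never be confused. How
detections from different methods should be identified as "the same
colloid" is genuinely open; object-level clustering is our choice, and a
pixel-level vote (`majority_vote_pixel()`: ≥ 2 of 3 masks) is provided for
comparison. Tie-breaks (distance, then method name, then position) make
the vote invariant to the order of the input sets, which the tests assert.

## Evaluation

Matching is greedy one-to-one by ascending distance with tolerance 3 px
(about twice the colloid radius; the matching rule needs *some* tolerance
and none is canonical). The conventions for pathological cases follow the
target-detection literature: extra detections near an already-matched
target are false alarms; one merged detection spanning two targets gives
one TP and one miss. Precision, Recall and F-measure use the 0/0 → 0
convention; TCR = DT/(DT+MT+FA) raises on all-zero counts since its
denominator vanishes only when nothing exists and nothing was predicted.
Metrics are computed per frame first and then averaged with a population
standard deviation — which is why the mean F-measure need not equal the
harmonic mean of the mean precision and recall.

Method comparison uses the Friedman test on the per-frame F-measures
(rank 1 = best, average ranks on ties, tie-corrected chi-square on k−1
degrees of freedom, cross-checked in the tests against
`stats::friedman.test` to 1e-9), followed by all pairwise rank-difference
z-tests `z = (R̄i − R̄j)/√(k(k+1)/6N)` with Holm step-down adjustment at
α = 0.05. The pairwise statistic after a Friedman test is not uniquely
standardized; the rank-difference z-test is the common default and is the
one implemented.

## The synthetic scene generator

`generate_scene()` emulates the structure of the real recordings, not
their optics. Grain geometry comes from a bilinearly upscaled smoothed
random field thresholded at the target porosity (0.42), with the threshold
iterated until the realized pore fraction is within ±0.02. The pore mask
is then regularized: closed with disk(3) to remove grain slivers, then
opened with disk(2). The opening makes the pore space exactly
disk(2)-open, which has a useful algebraic consequence: the grayscale
opening of the colloid-free scene with the top-hat probe reconstructs it
exactly, so the top-hat response of the background is identically zero and
every top-hat detection is a colloid. Physically this says the synthetic
pore throats are everywhere wider than the 5 px probe — true of the real
geometry at 2.9 µm/px, where pore throats span tens of pixels.

Colloids are stamped as disks of radius 1 (five pixels — a 4.3 µm particle
at 2.9 µm/px is ~1.5 px across) at integer positions, placed by rejection
sampling with ≥ 10 px pairwise separation (twice the vote radius) and a
6 px clearance from grains and the frame border. A fraction
(`frac_attached`, default 0.3: during active transport most colloids are
mobile, a minority attached) never moves; the rest advance each frame by a
rounded Gaussian step with mean 2 px along the flow — 4.8 m/day pore-water
velocity at 2.9 µm/px and 10 fps — re-drawn on collision with grains,
other colloids or the domain wall, which leaves some moves blocked
(realistic slow colloids, invisible to motion detectors). Colloids
passing the outlet are removed and replacements enter at the inlet, so
later frames vary in count. Optional Gaussian sensor noise (default off;
σ = 5 in the sensitivity tests) is added per frame and clipped. The whole
scene is a deterministic function of the configuration including its seed.

What the generator does **not** emulate: the microscope's point-spread
function (colloids are hard-edged disks, not Airy spots), photobleaching,
intensity gradients across the field of view, sub-pixel colloid positions,
and real attachment/detachment kinetics. Perfect scores on this benchmark
therefore demonstrate that the pipeline's logic is correct — each detector
sees exactly the structure it was designed for, and the ensemble's 2-of-3
rule cancels disjoint false alarms — not that the same numbers would be
reached on real microscope data, where blur, noise and drift erode the
margins. Conversely, two degeneracies the benchmark *does* expose are
real: on a strongly three-modal histogram the global Otsu threshold falls
at the dominant grain/pore split (the grain class holds ~58% of the mass),
so the Otsu and dilation+Otsu detectors mark the whole pore space
foreground and the area filter removes it — a genuine failure mode of
global thresholding on such scenes, recorded by the evaluation as missed
detections; and motion-based detectors score exactly zero recall when all
colloids are attached, which the tests assert as the family's defining
blind spot.

## Problem sizes and numerical choices

The test suite runs the benchmark at 256×256 px with 20 colloids and 27
frames (25 evaluated interior frames) — the geometry scales down cleanly
because all length parameters are in pixels — and exercises the full
1684×1688, 81-colloid geometry on a single frame. The acceptance script
runs the full-scale sequence end to end. k-means convergence is 1e-4 on
center movement; the DoG kernel is zero-sum to 1e-12; Otsu tie-breaks take
the smallest threshold; component labeling order is row-major and
deterministic; all detector masks are {0, 255} by construction. Degenerate
inputs fail loudly: constant frames are rejected by Otsu and k-means
(fewer distinct values than clusters), empty structuring elements and
mismatched shapes are argument errors.

## Limitations

Sub-pixel localization is not attempted (centroids are component means);
merged colloids closer than the component scale are not split (no
watershed); the ensemble is fixed at three constituents; and the Friedman
post hoc uses the rank-difference z-test only. Colloid tracking across
frames — linking detections into trajectories — is outside the package's
scope.
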