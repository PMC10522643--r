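---
title: "Fluorescence-derived landmark labels: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluorescence-derived landmark labels: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glowlabel)
```

## The problem

Markerless pose trackers are trained on images with landmark annotations,
and models trained on a few hundred manually labeled frames tend to be
hyper-specialized to one camera, one lighting rig, one behavior. A way out
is to generate labels automatically and at scale: mark the subject with a
dye that is invisible under visible light but fluoresces under UV
excitation, strobe the two light sources in alternation, and use the dye's
position in each UV frame as a "proxy label" for the adjacent visible
frame. The visible frames — in which the subject looks unmarked — become
training images with machine-generated annotations.

`glowlabel` implements the computational side of that pipeline twice over:

* the **serial route**, where a single landmark carries a solid dye mark
  and labels are blob centroids; and
* the **parallel route**, where an aerosolized dye speckle turns the whole
  surface into a field of *visual barcodes* — locally distinctive texture
  patches, operationalized as scale-invariant keypoints with descriptors —
  that are matched, filtered, and propagated from a small atlas of template
  images to every other frame.

Everything runs on synthetic imagery with analytic ground truth; no real
recordings or GPU training are involved. Training of the downstream
detector network is out of scope by design: the deliverables are the
labels, the stride-downsampled target maps, and the loss masks.

## Acquisition model

The reference capture runs on a 10 ms cycle (200 Hz frame rate): UV
illumination occupies one half-cycle and visible illumination the other,
with camera shutters at the half-cycle midpoints (2.5 ms and 7.5 ms,
2 ms exposure). `build_trigger_schedule()` models two variants:

* **biphasic** — the UV image is captured while the UV source is on; and
* **triphasic** — the UV source is extinguished at the first shutter
  trigger (2.5 ms with default parameters), so the UV image records only
  the dye's slow phosphorescent afterglow. Fast-decaying natural scene
  fluorescence and source bleed-through vanish, which is why the dye-mask
  stage can be a plain threshold.

`pair_frames()` matches each UV frame to the *next* visible frame of the
same camera. The pairing tolerance defaults to 1.5 times the schedule's
shutter offset: at 200 Hz adjacency is physically guaranteed, but an
explicit tolerance turns dropped frames into logged rejections rather than
silently bridged gaps (the capture literature does not say how dropped
frames were handled; we log and skip rather than interpolate). Pairs never
share a visible frame; when two UV frames precede one visible frame the
older one is rejected as superseded.

## Serial labeling

Per UV frame: threshold, morphological clean, centroid.

* **Threshold** — default Otsu on the intensity histogram with a fixed
  floor of 0.1. Under triphasic illumination the background is near-black,
  so almost any rule works; Otsu avoids per-setup tuning, and the floor
  prevents a histogram split of pure background noise when the dye is
  absent. A fixed numeric threshold is available.
* **Cleaning** — opening (radius 1) then closing (radius 2), removal of
  components under 20 px, at most 1 component kept. The reference design
  prescribes morphological cleaning but no values; these are conservative
  defaults for a blob a dozen pixels across, and `clean_mask()` is
  idempotent by construction.
* **Centroid** — the *unweighted* mean of mask pixel coordinates. The
  description says "centroid of the dye region", a statement about the
  region, not the intensities, so no intensity weighting is applied
  (intensity weighting is the obvious alternative; the difference on a
  symmetric blob is nil).
* **Absence is first-class** — an empty cleaned mask produces
  `present = FALSE`, and such frames are *retained*: a detector must also
  learn to stay silent, and absent frames are its negative examples.

Coordinates everywhere are 0-based pixel centers, x rightward, y downward.

Temporal interpolation (`interpolate_track()`) re-estimates each label at
the visible shutter instant from the neighboring UV-time samples, linearly
or with a natural cubic spline per coordinate (our reading of "bicubic"
for a 1-D time series, left undefined in the reference design). It is **off by
default**: at 200 Hz the 5 ms offset moves a fast-moving limb by well
under a pixel, and interpolation was found not to improve final metrics.
Absent runs longer than `max_absent_run` frames are never filled —
inventing labels across a real occlusion would manufacture false
positives.

## Visual barcodes

No scale-invariant feature implementation exists in this R stack, so the
detector is built here in the classical form: a difference-of-Gaussians
scale space (3 intervals per octave, base blur 1.6, starting from a 2x
upsampled octave so spots near one pixel in radius are interior extrema),
non-edge extremum selection, 3-d quadratic sub-pixel refinement, dominant
gradient orientation, and a 4x4x8 orientation-histogram descriptor,
normalized, clamped at 0.2, renormalized. Two numerical notes:

* extrema comparisons are *non-strict* with post-hoc deduplication,
  because exactly tied neighboring DoG values occur on synthetic imagery
  (bilinear upsampling creates them); a strict test silently drops such
  keypoints;
* the contrast threshold (default 0.01 on the [0, 1] intensity scale)
  applies to the interpolated peak response, matching the convention of
  the reference implementation it replaces.

The detector sits behind a seam: every downstream stage consumes plain
`feature_set` objects, so a different detector can be substituted.

Matching is nearest-descriptor with a Lowe ratio test (0.75) plus a
mutual-consistency check, one match per left keypoint. The acceptance
rule upstream of filtering is deliberately unremarkable: the pipeline's
robustness comes from the **spatial coherency filter**, which keeps a
putative match `(a, b)` only if some *different* match `(c, d)` satisfies
`|a - c| <= delta` and `|b - d| <= epsilon` (both 50 px by default,
Euclidean, boundaries inclusive — the inclusive choice is ours and is
pinned by tests at exactly 50.0). The filter uses an exact uniform-grid
neighbor index and is verified against a brute-force all-pairs oracle; it
is idempotent, order-preserving, and permutation-equivariant.

## Template atlas

To cover a long recording with few annotated templates, images are ranked
greedily: descriptors of the whole corpus are clustered; each feature's
weight is the number of *not-yet-covered* corpus features in its cluster;
an image's weight is the sum over its features; the heaviest image is
picked and every cluster it touches becomes covered. At desk scale the
original approximate half-million-cluster vocabulary is replaced by exact
Lloyd k-means (seeded), per the build contract. Two choices worth
recording:

* **Maximin initialization.** Random center initialization routinely puts
  two seeds in one descriptor mode and none in another; Lloyd cannot
  recover, merged clusters inflate image weights through multiplicity, and
  the greedy ranking degrades below random selection. Farthest-first
  traversal spreads the seeds across modes and makes the weight of a pick
  equal its realized coverage on separable corpora.
* **Whole-cluster covering.** Whether a picked image decrements clusters
  once or per feature multiplicity is ambiguous in the reference design; we cover
  whole touched clusters (the reading consistent with "all SIFT features
  that the selected image matches are marked as having been matched") and
  expose `per_feature_decrement = TRUE` as the alternative.

Ties in the argmax break toward the lowest image index. The post-hoc
manual refinement of the candidate list is modeled as a user-supplied
keep-list, not automated.

## Label propagation

**Manual neighborhoods**: filtered matches whose left endpoints fall in a
hand-drawn template region are pooled — across all templates supplying
that region — and the label is the per-axis median of the right endpoints
when at least `min_matches = 5` support it, else absent. Per-axis medians
may not coincide with any actual match point; accepted, since the median's
robustness is the point.

**Automatic neighborhoods**: landmark features are chosen by iterating
over candidates in a seeded random order and deleting everything within
30 px of each pick — a maximal spacing packing (tests assert maximality
and feasibility, never one particular packing). Candidacy is limited to
keypoints whose scale is at most one fifth of the neighborhood radius
(`max_scale_px`): a keypoint whose support region dwarfs its own pooling
neighborhood is a composite blob, localizes a couple of pixels coarse
under warps, and makes a poor point landmark — though it still
contributes as homography support. Per target frame the rule
is three-way: a landmark that matches directly takes its match location;
otherwise, if at least `k = 10` of its template neighbors (radius 30 px,
measured on the template — the target-side alternative is unstated in the
source and not implemented) matched, a local homography is fitted to those
neighbor correspondences and the landmark is projected through it;
otherwise absent. `k < 4` is refused outright — a homography needs four
correspondences.

The homography fit is a normalized direct linear transform. One deviation
from the original design sketch: the default fit is **trimmed least
squares** (`fit_homography_trimmed()` — fit, drop supports whose residual
exceeds `max(3 x median residual, 1 px)`, refit once). The coherency
filter's 50 px radii admit occasional support matches tens of pixels off;
a single such match in a 30 px neighborhood drags a plain least-squares
fit by several pixels, violating the pipeline's own 1.5 px recovery
contract. The trim is deterministic and is not RANSAC; plain DLT remains
available via `robust = "none"`. Degenerate (collinear) support is
detected through the second-smallest singular value of the design matrix
and falls through to absent with a warning.

## Training targets

`make_training_targets()` emits per-landmark confidence maps at
`ceil(image / stride)` resolution (stride 8 by default). The source
reports 86 x 86 maps for 848 x 848 inputs, but 848 / 8 = 106; the
discrepancy (cropping? internal padding?) is unexplained there, and we
implement the arithmetic definition. Semantics:

* present landmark: cells whose centers lie within `positive_radius_px`
  (default 17 input px — the downstream architecture's convention, not
  restated in the reference design, hence configurable) are 1, all else 0;
* landmark labeled *absent*: an all-zeros map with loss mask 1 — silence
  is supervised;
* roster landmark with *no label* in this image: loss mask 0, the
  **interleaved training** contract that lets single-landmark datasets be
  combined into one multi-landmark model.

Augmentation reproduces the reference recipe (blur sigma 0-0.5, contrast
0.75-1.5, additive noise sigma 5%, intensity scale 0.8-1.2, crop 0-10%,
affine scale 0.8-1.2, rotation +/-15 deg, shear +/-8 deg, grayscale with
probability 0.5 — a no-op on our single-channel images). The stated
translation range "0.8-1.2" is a unit confusion in the original
(percent-style parameters passed where a fraction was meant); we use
+/-10% of the image size, consistent with the crop range. Geometric
components transform labels identically — verified by planting a marker,
augmenting, and re-locating it — and labels pushed off-frame become
absent. Fluorescence segmentation (`make_segmentation_mask()`: threshold,
close, dilate) plus `composite_background()` implement the
random-background augmentation; backgrounds come from seeded multi-scale
value noise.

## Evaluation and scale optimization

The metric definitions are implemented literally: pixel error is Euclidean
distance where truth is present (absent-truth frames are excluded, not
scored zero); an *on-target* prediction has visible truth, confidence at
or above threshold (inclusive), and error strictly below 5% of image
width; recall divides by visible-truth frames, precision by
above-threshold predictions; the curve is traced at every distinct
confidence value. AUC integrates precision over recall by trapezoid after
sorting by recall, with a (0, first-precision) anchor — the integrator is
not pinned down by the reference definitions, and this choice makes a perfect detector
score exactly 1. A brute-force re-enumeration of the three conditions
serves as the test oracle.

Test-time scale optimization searches pre-scaling factors `2^k`, k from
-1 to 1 by 0.5, then `2^(k* + j)` for five fine offsets from -0.33 by
0.16 (the stated upper endpoint +0.33 is unreachable by that step; we
take exactly five steps). The objective is mean prediction confidence —
the smoothness (mean displacement) objective is implemented but off by
default, since smooth-but-wrong trajectories defeat it. The search
returns the argmax over *all ten evaluated points*, which makes it
provably identical to a flat sweep of the same composite grid for
unimodal objectives; ties break toward the earliest evaluated point.
Clip-level optimization shares one scale across the clip; frame-level
re-runs the search per frame. The detector adapter contract keeps
back-projection inside the adapter: predictions arrive in original-image
coordinates, so a detector that is truly scale-invariant produces
identical predictions at every scale (tested to machine precision with
the mock detector, whose positional noise is drawn once per frame for
exactly this reason).

## The synthetic world

`gen_serial_sequence()` renders a Gaussian dye blob (sigma 4 px, peak 0.9)
moving along a planted path over a near-black (0.02) textured background —
the triphasic regime — with occlusion frames that simply omit the blob;
visible frames carry an unrelated textured scene. `gen_speckle_scene()`
renders 500 Gaussian spots (sigma 1.2-2.2 px, intensity 0.45-1.0) inside a
foreground octagon and maps them through known translation/affine/
projective warps, exposing the warp matrices as the analytic
correspondence oracle. Spots are smooth Gaussians rather than hard disks
deliberately: hard edges alias under resampling and destabilize keypoint
localization in a way real speckle does not. `gen_coherent_matches()`
plants jittered-grid true matches (every one guaranteed a coherent
neighbor at the 50 px radii) plus feature-level spurious injections whose
right endpoints ignore the warp, so filter removal rates are measurable
against a plant list.

What the generators do *not* emulate: fur and specular skin, perspective
foreshortening of a 3-D limb, dye smearing and decay, motion blur, sensor
noise correlations, or multi-camera geometry. A green test therefore
establishes algorithmic correctness against the stated model — thresholds
separate, warps are exact, descriptors see mild projective distortion —
not field performance on real recordings; the reference pipeline's headline
accuracy numbers depend on training a deep network on hundreds of
thousands of real images and are out of reach (and out of scope) here.

## Known limitations

* The feature detector is a faithful but compact reimplementation; it has
  one orientation per keypoint (no secondary-peak duplication) and no
  descriptor caching, and at ~2 s per 256 x 256 frame it is meant for
  fixture-scale corpora, not 12,000-frame videos.
* Exact k-means replaces the approximate vocabulary tree; complexity is
  linear in corpus size per iteration and the 500,000-cluster regime is
  explicitly not reproduced.
* `pool_manual_neighborhood()` expects its caller to have pooled
  multi-template matches per region; the package supplies the grouping
  helper but no annotation UI.
* The pipeline runner covers the serial route end to end; the parallel
  route is exercised through the library API (template selection and
  propagation involve judgment calls — which templates to keep, which
  region masks — that a config file would only obscure).
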