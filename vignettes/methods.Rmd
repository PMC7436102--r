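---
title: "Methods: two-view food volume estimation with gravity-aided pose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-view food volume estimation with gravity-aided pose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the model

Estimating the energy and macronutrient content of a meal from photographs
decomposes into four questions: *where* is each food item (segmentation),
*what* is it (recognition), *how much* of it is there (3D volume), and what
does that imply nutritionally (a per-100-ml composition lookup). mealvision
implements this pipeline at desk scale, with a synthetic tabletop world
that supplies analytic ground truth for every stage.

## Coordinate conventions

Pixels have integer-centered coordinates, origin at the top-left pixel
(1,1), `u` along columns and `v` along rows; images are
`array(height, width, 3)` in `[0, 1]`. The world frame is metric (mm) and
anchored on the reference card: card center at the origin, long edge along
`+x`, table plane `z = 0`, `z` up. Poses map world to camera
(`x_cam = R x + t`), with the camera `z` axis along the optical axis and
`y` down. These conventions are load-bearing for the bit-exact tests and
are asserted throughout the suite.

## Metric pose: reference card plus gravity

A credit-card-sized object (ISO ID-1, 85.60 × 53.98 mm) anchors the metric
scale. Detection finds the brightest large component, closes it
morphologically (the card's dark magnetic stripe would otherwise split it),
reduces the boundary to a convex quadrilateral, refines each edge by
total-least-squares line fitting, and then re-localizes each edge
photometrically: the luminance profile across the edge is sampled
bilinearly and the 50% crossing interpolated, which recovers the sub-pixel
edge position that anti-aliased (pixel-integrated) images carry. Corner
ordering is fixed by two cues: the image-plane winding (a camera above the
table always sees the same orientation of the corner cycle) and the stripe
(which breaks the rectangle's 180° symmetry). Without the stripe, planar
pose from a plain rectangle is ambiguous up to a 180° yaw; a real detector
would use the card's printing instead.

Pose follows from the standard planar decomposition `H ≃ K [r1 r2 t]` with
cheirality fixing the sign, orthonormalization by SVD, and a reprojection
polish.

The IMU gravity vector `g` (unit, camera frame) then does two jobs:

1. *Table orientation for free:* the table is assumed horizontal, so its
   upward normal in camera coordinates is simply `-g`.
2. *Tilt elimination in pose estimation:* any rotation consistent with
   gravity can be written `R = A(g) Rz(φ)` where `A(g)` is the minimal
   rotation taking world-down onto `g`. The two tilt degrees of freedom are
   fixed analytically; only the yaw `φ` (1 DoF) and translation (3 DoF,
   scale from the card) are estimated from correspondences — a 1-D search
   with a linear least-squares translation solve per candidate yaw, plus a
   joint polish. On noiseless data this equals the unconstrained planar
   estimate to 1e-6 (tested), and under noise it is more stable because
   fewer parameters compete for the same four corners.

Because the plane-sweep matcher converts *any* residual inter-view warp
misalignment directly into height bias, the pipeline adds a dense
refinement: ~350 textured background pixels (table-plane by segmentation;
the card counts as plane) are matched by an unconstrained local NCC search
with sub-pixel parabolic interpolation, and the gravity-constrained yaw and
translation are re-solved on those matches. This one step reduced
end-to-end volume error from roughly −13% to under 5% in our development
measurements — the single most consequential design choice in the geometry
stack.

## Dense matching and triangulation

Matching is plane-sweep NCC: each table-height hypothesis `z = h` induces a
warp of view 2 into view 1; per-pixel NCC over an odd window picks the best
`h`, refined by parabolic interpolation, with a symmetric left-right check.
Fronto-parallel sweeps systematically flatten sloped surfaces (the window
content shears between views), so up to `refine_iters` slope-aware passes
re-sweep a ±3 mm offset with *per-pixel* warps that follow the current
surface estimate. Three passes cut the bias on a 30 mm spherical cap from
about −4% to under −3% at the working resolution, converging geometrically.

Parameter defaults and why:

| parameter | op default | pipeline default | rationale |
|---|---|---|---|
| NCC window | 11 px | 7 px | 11 px spans >20 mm of table at ~2 mm/px and flattens relief; on megapixel photographs 11 px is appropriate |
| refinement window | = window | 5 px | smaller windows reduce boundary mixing once the surface estimate is close |
| LR tolerance | 1 px | 1.5 px | sub-pixel interpolation quantization near rims exceeds 1 px at this resolution; 1 px drops rim support and shrinks footprints |
| min NCC | 0.5 | 0.3 | rim windows mix item and table content; dropping them loses footprint area, which costs more volume accuracy than the occasional weak match |
| height step | 1 mm | 1 mm (4 mm coarse pass in rig mode) | ~0.2 px disparity per mm at the default geometry |

Triangulation is per-point linear least squares on the four projection
equations (vectorized via Cramer's rule), with reprojection residuals
stored and behind-camera points excluded. The nonlinear
reprojection-minimizing oracle in the test suite agrees to 1e-6 mm on
noiseless pairs.

In stereo-rig mode (dual-camera phone; known baseline, no card) the world
frame is anchored on camera 1, so the table depth is unknown a priori: a
coarse 4 mm sweep over plausible capture distances locates the plane, and
the fine sweep is re-anchored around it.

## Plane and volume

The plane normal is *never* estimated from the cloud — it comes from
gravity, bit-for-bit. Only the offset is fitted, as the median of
background-point heights, which tolerates ~30% contamination by food
points. Each item's points are projected to the plane, gridded (1 mm
default), per-cell heights are medians clipped at zero, the footprint is
the morphological closing of the support cells at the measured point
spacing (so the exterior flood cannot leak between sparse samples),
enclosed holes are filled from neighbours, and cells outside the footprint
contribute nothing. Food height is measured above the *table* plane: plated
real meals would be overestimated by the plate's thickness; modelling a
plate interior surface is out of scope and flagged as a limitation.

## Segmentation

Seeded region growing and merging in CIE Lab (ΔE 1976): each user stroke is
flooded 4-connectedly to pixels within `tau_grow` of a reference color, in
two stages — a conservative half-threshold flood harvests the item's core,
whose mean replaces the noisy few-pixel stroke mean as the reference for the
full flood. A final competition pass assigns unclaimed pixels bordering a
region to it when their color is closer to the region mean than to the
background mean (gated at `2 * tau_grow`, so the degenerate
`tau_grow = 0` contract — regions equal their seeds exactly — is
preserved). Adjacent regions whose means differ by less than `tau_merge`
merge; unclaimed pixels are background. Growth uses fixed references and
synchronous wavefronts, so results are independent of stroke order.

Defaults `tau_grow = 20`, `tau_merge = 12` were derived once from the
synthetic world's color geometry: the interior within-item spread is below
14 ΔE at the 99.5th percentile while every food family stays ≥ ~30 ΔE from
the table cloud, leaving the threshold a comfortable margin on both sides.

Fmin/Fsum follow a documented convention: greedy one-to-one maximum-overlap
matching; unmatched truth items score 0 (and so dominate Fmin); unmatched
*predicted* items count only against the pooled Fsum. Under that convention
`Fmin ≤ Fsum` holds whenever the prediction has no more items than the
truth — which is the seeded segmenter's entire output space (one region per
seed, merges only) — but is provably violated by spurious extra predicted
items (a perfect match plus one disjoint false-positive item gives
Fmin = 1 > Fsum). The property test asserts the inequality on the valid
domain and the counterexample explicitly.

## Recognition

The three-level hierarchy (fine-grained → hyper-2 → hyper-1) is a CSV-backed
tree with single-parent invariants. The classifier is one shared backbone
with three parallel linear-softmax heads sized to the level cardinalities,
trained jointly on the summed cross-entropies with plain SGD at the
published recipe (lr 1e-2, batch 32, 20 epochs). The desk-scale backbone is
a fixed grid-statistics feature extractor with a constant affine input
normalization (not data statistics) so the fixed learning rate moves the
logits at a useful rate; a deep backbone can be plugged in behind the same
interface. Weighted inference takes each level's weight times its maximum
softmax probability; the fine level is excluded when its *unweighted*
maximum probability falls below `fallback_threshold` (keeping the rule
invariant to weight rescaling, which is also a tested property); ties break
toward the finer level because finer categories carry more specific
nutrient records. Weights default to uniform and the threshold to 0.5 —
declared defaults, not claims about any production system.

One caveat the tests make visible: the synthetic classification set
guarantees linear separability of the *fine* classes (distinct color
families); hyper categories are unions of arbitrary families and need not
be linearly separable, so hyper-head training accuracy is typically lower.
Only the fine-grained smoke contract (≥ 90% training accuracy within the
published budget) is asserted.

## Nutrition and evaluation

Nutrients are exactly linear: `value = volume_ml / 100 × per_100ml`, by
volume rather than mass (no density table — a modelling simplification
inherited from the per-100-ml accounting basis). Missing fine-grained keys
fall back to the hyper-category record, explicit if present, otherwise the
mean of the tabulated children, with provenance recorded; the fallback can
never shadow a resolvable fine-grained key.

Evaluation implements the field's standard agreement toolkit: median
absolute error with 25th/75th percentiles (linear interpolation between
order statistics — R's type-7 convention, stated because conventions
differ), MARE (items with non-positive truth excluded, with a warning),
Pearson r, Bland–Altman mean difference with ±1.96 SD limits, and a
one-sided Welch t-test on two methods' absolute errors (unpaired; the
"two-sample" phrasing suggests unpaired, and a paired variant would be a
one-line change). The Welch statistic is hand-implemented because
zero-variance degenerate samples need an exact-equality fast path that
`t.test` refuses.

# The synthetic world

`make_scene()` ray-casts parametric solids — spherical caps, cylinders,
cuboids, half ellipsoids, all with closed-form volumes — on a textured
plane with the reference card, at the 90°/75° elevation pair, 400 mm
distance, 200 × 150 px by default (about 2 mm per pixel on the table).
Surfaces are flat-shaded procedural value-noise textures: *additive
achromatic* (luminance) noise over per-class base colors, because the block
matcher needs luminance contrast while the segmenter needs stable chroma
separation; multiplicative color noise makes saturated hues span > 25 ΔE
internally and collide with the table's color cloud. Class base colors are
saturated hues kept ≥ ~40 ΔE from the brown table. Images are
pixel-integrated (2 × 2 supersampling) by default; ground-truth masks are
then defined as each pixel's *majority* content, matching what the image
shows. Exact sub-pixel correspondences come from re-casting rays and
comparing first hits (a z-buffer visibility test).

What a green test does and does not establish: the world has no plates or
plate rims, no shadows or specular highlights, no lens distortion, no
motion blur, and food colors are deliberately separable from the
background. Green acceptance tests establish that the geometry is correct
and the algorithms meet their contracts under honest image formation
(pixel integration, texture, occlusion); they do not establish real-food
accuracy, which in the source study was measured on real databases with
trained networks.

Numerical/degenerate-input choices worth knowing:

- At exact nadir, gravity is anti-parallel to the camera's world-down and
  the minimal rotation `A(g)` is undefined; a fixed 180°-about-x frame is
  used, the yaw DoF absorbing the arbitrary choice.
- The pixel-disagreement contract for segmentation is asserted on
  hard-edged renders (`supersample = 1`): with pixel integration the
  one-pixel boundary ring is a physical color mixture whose label is
  intrinsically ambiguous at ~2 mm/px, so anti-aliased renders are held to
  the Fmin ≥ 0.95 floor instead.
- Monte-Carlo acceptance runs (50 scenes × 2 baselines) use
  `supersample = 1` purely for speed: those criteria consume exact
  ray-cast correspondences, not rendered pixels.
- Top-k ties (an untrained model outputs exact ties) are broken uniformly
  at random; seed the RNG for reproducibility.

# Known limitations

- Volumes are measured above the table plane; plated meals would be
  overestimated by the plate's displaced volume.
- Per-100-ml accounting ignores density; real tables are usually per-100-g.
- The stripe-based card orientation stands in for printed-card cues; a
  plain white rectangle leaves a 180° yaw ambiguity that only scene content
  can break.
- The ~20 cm two-view baseline at 40 cm range is near the comfortable limit
  for a 7 px NCC window; much larger baselines would need affine-adapted
  matching.
- The desk-scale backbone separates color/texture families only; it is a
  stand-in for a deep backbone behind the same interface, not a food
  recognizer.
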