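---
title: "Cross-modal RGB-IR mapping for head-region thermometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal RGB-IR mapping for head-region thermometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermomap)
```

## The measurement problem

Thermal cameras report a temperature per pixel, but at low resolution
(384 x 288 here) and with little texture, so outlining a small anatomical
region — a chicken's comb, eye, beak or wattle — directly in the infrared
image is unreliable. A dual-channel camera also carries a high-resolution
RGB sensor (2688 x 1520) in which those regions segment well. `thermomap`
transfers segmentation masks from the RGB frame to the IR frame so that
region temperature statistics can be computed over masks that follow the
true region outlines rather than coarse boxes.

## The mapping model

Both channels are pinhole cameras with Brown–Conrady lens distortion.
For a pixel $(u, v)$ in the RGB image the per-point transfer chain is:

1. **Normalize**: $x = (u - c_x)/f_x$, $y = (v - c_y)/f_y$ using the RGB
   intrinsics.
2. **Undistort**: invert the Brown–Conrady model
   $x_d = x(1 + k_1 r^2 + k_2 r^4 + k_3 r^6) + 2p_1xy + p_2(r^2+2x^2)$
   (and symmetrically for $y_d$) by fixed-point iteration.
3. **Back-project** onto the working plane: $P = (x\,d,\; y\,d,\; d)$,
   where $d$ is the scalar working depth in mm — the distance from the
   RGB channel to the target plane. The subject is treated as lying on a
   fronto-parallel plane at that depth (the acquisition protocol fixes it
   at 600 mm with a ruler).
4. **Transform** rigidly into the IR camera frame:
   $P' = R\,P + t$ with the rig extrinsics $(R, t)$.
5. **Re-project** through the IR intrinsics and distortion to continuous
   IR pixel coordinates.

Whether the source material applies distortion correction in pixel or in
normalized coordinates is ambiguous; the two formulations are
mathematically equivalent for this model, and the package normalizes
first and undistorts in normalized space, which is the numerically
standard route.

At the mask level (`map_label_mask()`), the outer contour of each
8-connected component of a region is traced (Moore neighbor tracing over
boundary pixel centers, counter-clockwise, components under `min_area = 5`
px discarded as segmentation specks), every vertex is pushed through the
chain above, and the mapped polygon is closed and filled on the IR grid.
Mapped regions are kept as independent binary masks — projection can make
them overlap, and flattening would silently destroy pixels a thermometry
user needs; an optional flattening writes comb, wattle, beak, eye in that
order so the smallest structures win ties.

### Numerical choices

* **Coordinates**: 0-based, $(u, v)$ = (column, row), integer
  coordinates at pixel centers — the dominant computer-vision
  convention.
* **Undistortion** uses the classical fixed-point iteration
  $x \leftarrow (x_{obs} - \mathrm{tangential}(x))/\mathrm{radial}(x)$
  with tolerance $10^{-10}$ on normalized coordinates and at most 50
  iterations; non-convergence (possible for extreme coefficients at
  large radius) is an error naming the offending point, never a silent
  pass-through.
* **Fill rule**: a pixel belongs to a mask iff its center lies inside
  the closed polygon under the nonzero winding rule, with centers
  exactly on an edge counting as inside. The production implementation
  is an exact scanline fill; a per-pixel winding-number implementation
  is kept internally and the two are asserted identical on random
  (including self-intersecting) polygons.
* **Degenerate inputs**: contours with fewer than 3 points rasterize to
  an empty mask with a warning; polygons wholly outside the image clip
  to empty; points behind a camera ($Z \le 0$) and non-positive depths
  are errors.
* The pixel-center contour convention makes mapped masks sit
  systematically about half an RGB pixel inside the true region
  boundary (~0.12 IR px at this resolution ratio). This is inherent to
  the convention (shared by the standard contour-following tools), is
  far below the IR pixel pitch, and cancels entirely in
  baseline-relative comparisons such as the depth sweep.

## Rig calibration

`calibrate_rig()` implements Zhang's planar-checkerboard method for both
channels: plane-to-image homographies by normalized DLT, closed-form
intrinsics from the homography constraints, per-pose extrinsics, then
full Levenberg–Marquardt refinement (via `minpack.lm`) of intrinsics,
five distortion coefficients and poses per channel, and finally a joint
two-channel bundle that refines the RGB-to-IR extrinsic transform
(initialized by averaging per-pose relative transforms, rotations
averaged through the SVD). The board is the 15 x 16 array of 25 mm
squares (14 x 15 = 210 inner corners) heated so corners are visible in
both channels; corner detection itself is out of scope — observations
enter as coordinates.

Fewer than 3 poses, or any pose with an incomplete corner grid, is an
insufficient-data error; a poorly conditioned pose set (near-degenerate
homography constraints) yields a warning and a best-effort result. On
noiseless synthetic corners the generating rig is recovered to well
under 0.1 % (intrinsics) and 0.1 mm (translation); with 0.1 px corner
noise and 10 poses, intrinsics are typically recovered to ~0.5 %, with
the IR principal point the widest parameter (the IR channel sees the
board at weak perspective, which is the information-theoretic
bottleneck, not an optimizer artifact).

## Depth-error sensitivity

The working depth enters only through step 3, so a depth error moves
every mapped point along the epipolar direction. For a distortion-free
rig with pure baseline $b$ and IR focal length $f$, mapping at depth
$d'$ instead of $d$ shifts every point horizontally by exactly
$f\,b\,|1/d - 1/d'|$ — the closed form used as an oracle.
`sweep_depths()` reproduces the sweep protocol: depths 580–620 mm in
1 mm steps around the 600 mm baseline, each depth's per-region masks
compared with the *baseline-depth mapped masks* (not ground truth,
matching the protocol) by IoU and centroid offset, averaged over frames.
The baseline row is an exact fixed point (IoU 1, offset 0) by
construction. Frames in which a region is empty at baseline are skipped
for that region with a tally, since IoU is undefined there.

Monotone-trend diagnostics in `summarize_sweep()` use small tolerances
(IoU $10^{-3}$, offset 0.01 px): masks are rasterized, so a single
boundary pixel can tick a mean IoU up even though the underlying
continuous-geometry trend is strictly monotone.

## Segmentation evaluation and losses

Evaluation pools a $k \times k$ pixel-count confusion matrix (default
$k = 5$: background, comb, eye, beak, wattle). Per-class
$\mathrm{IoU}_i = p_{ii} / (\sum_j p_{ij} + \sum_j p_{ji} - p_{ii})$;
MIoU is its mean; MPA is the mean per-class recall
$p_{ii}/\sum_j p_{ij}$ — the literal reading of the mean-pixel-accuracy
definition. Classes absent from both truth and prediction are excluded
from the means (0/0 is undefined) and reported; background participates
by default with a flag to restrict to the four head regions. MIoU never
exceeds MPA because the IoU denominator is never smaller than the recall
denominator.

The loss surface carries the class-imbalance tools used when training
small-region segmenters: focal loss
$FL(p_t) = -\alpha (1-p_t)^\gamma \log p_t$ (defaults
$\alpha = 0.25, \gamma = 2$, the originating convention — the source
material cites focal loss without stating values), dice loss with the
conventional smoothing $\varepsilon = 1$, BCE, and a combined mask loss
with configurable weights (1:1 by default, also unstated upstream).
Training itself is a non-goal: segmentation is a pluggable contract
(image in, label mask out, declared class table) with a reference
segmenter that inverts the synthetic scene color table — exact in
strict mode, nearest-color under noise.

## The synthetic scene generator

No dataset accompanies the source material, so the generator *is* the
study's test bed, and its defaults are the study conditions:

* **Rig** (`"paper-like"` preset): the printed resolutions
  (RGB 2688 x 1520, IR 384 x 288), IR focal length ~588 px (a 17 µm
  pitch core behind a 10 mm lens), RGB focal length ~2400 px, an
  X-dominant baseline of ~47 mm with sub-degree convergence, mild
  barrel distortion ($k_1 \approx -0.09$ RGB, $-0.18$ IR), emissivity
  0.96 and ±0.5 °C accuracy as metadata. The true rig parameters are
  unprinted, so this is an emulation of plausible optics, not a
  reconstruction; with it, the depth sweep lands on the same magnitudes
  the source reports (offset ≈ 0.17 px at ±2 mm, ≈ 1.6 px at 20 mm,
  IoU ≈ 0.98 at ±2 mm) without any tuning toward them.
* **Head regions**: convex/star polygon templates in millimetres on the
  600 mm plane — serrated comb crown, large eye disc (r = 9 mm), beak
  wedge, wattle lobe, ~9 cm head overall — sized so the smallest region
  spans ~19 IR px across, enough for stable mask statistics;
  biological realism beyond that is a non-goal. Placement jitter
  (±15 mm, ±10°, ±10 % scale) varies framing per seed.
* **Temperatures**: a low-order polynomial background over 26–30 °C;
  inside a region the field equals the region's generating mean (comb
  39.5, eye 40.5, beak 33.0, wattle 39.0 °C — eye and the vascularized
  comb/wattle warm, keratinized beak cool), so that noiseless recovery
  is exact by construction; i.i.d. Gaussian pixel noise (σ = 0.3 °C)
  on top. Heat-stress scenes raise comb/wattle by 2.5 °C, the scale of
  contrast reported for heat-stressed birds.
* **Checkerboard poses**: tilts of 12–35° with random sign (bounded
  away from frontal, which carries no principal-point information),
  distances chosen so the full grid fits the IR frame, full-visibility
  rejection sampling, optional Gaussian corner noise.
* **Oracle independence**: ground-truth IR masks are produced by
  projecting the generating polygons directly through the rig geometry,
  never through the contour-mapping path; agreement between the two
  routes is a test result.
* **Oracle presets**: the `"parallax"` (pure baseline, zero distortion)
  and `"zero-baseline"` presets exist for closed-form checks. The
  parallax preset uses smooth elliptical region blobs at twice the
  scale and a half-resolution RGB channel: polygon templates with long
  axis-aligned edges quantize mask centroids coherently across rows
  (errors up to ~0.4 px), while ellipses decorrelate rows and leave the
  pooled centroid offset within ~0.03 px of the closed form.

Everything is a pure function of (spec, seed); one seeded generator
drives each scene and seeds are echoed in the scene metadata.

### What passing tests do and do not show

The generator emulates geometry, radiometric noise and the color coding
a segmenter inverts. It does not emulate feathers occluding region
roots, specular or emissivity variation, motion, defocus, or
segmentation errors of a trained network on real birds. Passing tests
therefore validate the *mapping, calibration, evaluation and
thermometry machinery* under known geometry — they do not certify
segmentation accuracy on real animals, which in the source pipeline
comes from trained models outside this package's scope.

### Statistical form of the end-to-end checks

The end-to-end suite runs 20 seeded scenes through segmentation,
mapping and thermometry. Region-mean temperature recovery is asserted
on the pooled (across-trials) per-region error against its sampling
bound $2\sigma/\sqrt{n_{pooled}}$ with a Bonferroni factor (2.5σ per
region ≈ 2σ family-wise over four regions); a literal per-region 2σ
assertion is a 95 % probabilistic statement that would fail a few
percent of seeds by construction. Mask agreement with the
direct-projection ground truth is asserted on the per-region mean IoU
over the ensemble (observed ~0.97–0.98; single scenes fluctuate by a
few boundary pixels at 384 x 288). The closed-form parallax comparison
pools regions and frames per depth, matching the average-over-all-pairs
sweep protocol.

## Problem sizes

Tests and the acceptance script use: 20 rigs x 40 points for the
mapping oracle; one noiseless and one noisy calibration (10 poses x 210
corners x 2 channels); 3 parallax frames and 6 realistic frames x 41
depths for the sweeps; 20 full-resolution scenes (plus 20 paired
heat-stress scenes) for the end-to-end pipeline; 20 mask pairs and
1,000 random confusion matrices for the metric checks. These sizes keep
the full suite at a few minutes on one CPU while leaving every
tolerance dominated by the quantity under test rather than by sampling
noise.

## Known limitations

* A single scalar depth per frame (fronto-parallel plane); per-point
  depth maps and occlusion reasoning between mapped regions are
  non-goals.
* Outer contours only; interior holes in a region are filled. Head
  regions are simply connected in practice.
* No radiometric, emissivity or distance compensation — the camera
  applies emissivity internally and the value is carried as metadata.
* Sub-pixel mask anti-aliasing is not modelled; all masks are hard.
* The calibration delegates its nonlinear optimization to
  Levenberg–Marquardt with numerical Jacobians; for very large pose
  counts an analytic-Jacobian bundle would be faster, but at the
  protocol's 10 poses the joint solve takes seconds.
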