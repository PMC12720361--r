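# thermomap

Cross-modal RGB–infrared mapping for region-based animal thermometry.

## The problem

Surface temperature of the featherless chicken head regions — comb, eye,
beak, wattle — is a practical indicator of heat stress, and dual-channel
cameras capture a high-resolution RGB image (2688 × 1520) alongside a
low-resolution thermal matrix (384 × 288, °C per pixel). Segmenting the
head regions is easy in the RGB frame and unreliable in the blurry IR
frame, but the temperatures live in the IR frame. `thermomap` is the
bridge: it calibrates the dual-channel rig and transfers RGB
segmentation masks into the IR pixel grid so temperature statistics are
computed over masks that follow the true region outlines rather than
boxes that leak background.

It is aimed at people building precision-livestock or veterinary
thermography pipelines in R, and at anyone who needs a tested
implementation of RGB→thermal mask transfer with a depth-error analysis.

## The method

Each channel is a pinhole camera with Brown–Conrady distortion. A region
mask is transferred contour point by contour point:

1. normalize by the RGB intrinsics: `x = (u − cx)/fx`, `y = (v − cy)/fy`;
2. undistort (fixed-point inversion of
   `x_d = x(1 + k1 r² + k2 r⁴ + k3 r⁶) + 2p1 x y + p2(r² + 2x²)`);
3. back-project onto the working plane at depth `d` (mm): `P = (x d, y d, d)`;
4. transform rigidly into the IR frame: `P′ = R P + t`;
5. re-project through the IR intrinsics and distortion.

The mapped contours are closed and filled (nonzero winding,
edge-inclusive) on the IR grid. Rig parameters come from Zhang
checkerboard calibration (`calibrate_rig()`, 15 × 16 board of 25 mm
squares, Levenberg–Marquardt refinement, joint two-channel bundle).
Because the whole transfer hinges on the scalar depth (600 mm in the
acquisition protocol), `sweep_depths()` quantifies the sensitivity:
masks mapped at 580–620 mm are compared with the baseline-depth masks
by IoU and centroid offset — for a distortion-free rig with pure
baseline `b` the offset is exactly `f · b · |1/600 − 1/d|`.
Segmentations are scored with per-class IoU, MIoU and MPA from a pooled
confusion matrix, and the focal/dice/BCE losses used for small-region
segmenters are provided. A seeded synthetic-scene generator (rigs,
checkerboard observations, head-region masks, ground-truth IR masks by
direct projection, temperature fields) serves as the test bed; trained
segmentation networks are out of scope behind a pluggable contract.

## Worked example

```r
library(thermomap)

spec  <- scene_spec("paper-like", seed = 7)   # emulated dual-channel rig + scene
scene <- make_scene(spec)
rig   <- scene$rig

seg <- reference_segmenter(scene$rgb_color)   # stands in for a trained model
roi <- map_label_mask(seg, rig, depth = 600)  # RGB mask -> IR masks
roi
#> roi_set (288 x 384 px, depth 600.0 mm)
#>   comb      1110 px  (out-of-bounds fraction 0.000)
#>   eye        280 px  (out-of-bounds fraction 0.000)
#>   beak       545 px  (out-of-bounds fraction 0.000)
#>   wattle     615 px  (out-of-bounds fraction 0.000)

region_stats(scene$temps, roi)
#>   region   mean_c    min_c    max_c pixel_count
#> 1   comb 39.49607 38.54331 40.54353        1110
#> 2    eye 40.47558 39.43595 41.22532         280
#> 3   beak 32.99758 32.18158 33.98476         545
#> 4 wattle 38.99730 38.18513 39.94138         615
```

The scene was generated with comb/eye/beak/wattle at 39.5/40.5/33.0/39.0 °C
plus 0.3 °C pixel noise; the mapped-mask means recover the generating
values to a few hundredths of a degree, i.e. within sampling error of
the pixel counts. `out_of_bounds` bookkeeping flags contour points that
map outside the IR frame, and `sweep_depths()`/`summarize_sweep()`/
`plot()` reproduce the depth-sensitivity analysis
(`mean offset ≈ 0.17 px at ±2 mm` on this rig — small against the IR
pixel pitch, which is why a ±2 mm positioning tolerance is acceptable).

A thin CLI over the same functions lives at `inst/cli/thermomap.R`
(`simulate`, `map`, `eval-seg`, `sweep-depth`, `measure`), e.g.

```sh
Rscript inst/cli/thermomap.R simulate --preset paper-like --seed 7 --out-dir scene7/
Rscript inst/cli/thermomap.R map --rig scene7/rig.json --mask scene7/rgb_mask.png \
    --depth 600 --out-dir roi7/
Rscript inst/cli/thermomap.R measure --roi-dir roi7/ --temps scene7/temps.csv --out temps.json
```

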