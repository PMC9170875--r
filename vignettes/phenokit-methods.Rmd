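---
title: "Methods: canopy trait extraction from RGB, depth and thermal imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy trait extraction from RGB, depth and thermal imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenokit)
```

`phenokit` implements the image-analysis side of an automated phenotyping
rig for chamber-grown wheat: a gantry carries an RGB camera, a
pre-registered depth camera and a radiometrically calibrated thermal camera
over a grid of round root boxes (inner diameter 15 cm), imaging each box
vertically from a 0.6 m standoff. This vignette documents the models behind
each trait, the tunable parameters and their defaults, the numerical
choices, what the synthetic scene generator does and does not emulate, and
the known limitations.

All modules share one pixel convention: coordinates are (row, col) with the
origin at the top-left. Depth is carried in millimetres with 0 as the
sensor's invalid-return sentinel; heights are converted to centimetres
exactly once, when a `height_measurement` is formed.

## Green index and leaf area (RGB)

The green index is the fraction of image pixels classified as vegetation in
the vertical canopy projection. Two classifiers are available through
`green_params()`:

* **excess green** (default): a pixel is vegetation iff
  `2G − R − B > τ` with `G > R` and `G > B`. τ defaults to 20 on the
  0–255 scale; smaller values are more permissive, and the resulting green
  index is monotone non-increasing in τ. The excess-green statistic is the
  standard vegetation index for RGB-only segmentation and needs no
  per-image tuning.
* **channel threshold**: the G-channel histogram is binarized at its
  between-modes valley (below), matching the histogram-driven description
  of the original acquisition software. It is kept as the literal
  alternative; excess green is the default because a single fixed rule
  behaves predictably across the growth stages.

Leaf area uses reference-calibrated pixel counting. A disk of known area
$S_1$ covering $P_1$ pixels fixes the unit pixel area, and a canopy of $P$
leaf pixels has

$$S = \frac{S_1}{P_1}\,P .$$

The identity is exact and linear in $P$, and because only the ratio
$P/P_1$ enters, the result is invariant to uniform image rescaling — both
properties are asserted in the test suite. The reference disk matches the
box's 15 cm inner diameter; with the legacy convention $\pi = 3.14$ its
area is the calibration constant 176.625 cm² (`reference_area(15, 3.14)`),
while the package default uses machine π (a 0.05 % difference that cancels
in relative comparisons).

The extraction chain is: green segmentation → median filter (3×3) →
small-object removal (components < 25 px; the threshold is configurable,
chosen as the smallest speck plausibly distinguishable from a leaflet at
the default scale of ~13 px/cm) → reference detection → pixel counting.

The reference can be photographed separately (**calibration-image mode**,
the default: the frame contains only the disk, so the largest component is
the reference) or share the canopy frame (**in-scene mode**). Because the
reference is deliberately the same green as the crop, in-scene mode must
separate it by *shape*: among components within ±30 % of the expected disk
area (from a caller-supplied px/cm hint), the one with the highest
circularity $4\pi\,\mathrm{area}/\mathrm{perimeter}^2$ above 0.8 is taken,
and its pixels are excluded from the leaf count. Perimeter is estimated by
the two-direction Crofton formula, $\pi/4$ times the count of
foreground/background 4-adjacent pixel edges; this makes a rasterized disk
score ≈ 1.0 (62 px radius disk: 0.999) while elongated leaf blobs score
0.3–0.45. The estimator is exact in expectation for disks but overrates
axis-aligned rectangles (a square scores 4/π ≈ 1.27), which the area
window mitigates; scenes whose leaves are compact axis-aligned squares
would defeat it, wheat leaves do not.

## Plant height (depth)

Height is the difference of two camera distances,

$$H = h_2 - h_3,$$

with $h_2$ the camera-to-soil-surface distance and $h_3$ the
camera-to-leaf distance. The characteristic points are the **leaf center**
— the junction of the leaves (main stem), realized as the foreground pixel
nearest the plant-mask centroid, which is guaranteed to lie on the mask —
and the **soil center**, the nearest non-plant pixel to the leaf center.
Nearest-pixel searches break ties to the smallest row, then column, so
results are deterministic.

Single-pixel reads of consumer depth sensors are unreliable, so each depth
lookup is the median of the valid (non-zero) depths in a 5×5 patch, and the
pipeline averages `n_repeats = 5` lookups at deterministically jittered
centers (radius 2 px, seeded). The repeat count follows the
repeat-and-average protocol of the original rig, which does not state a
count; five repeats leave the noise-free result exact while averaging
sensor noise.

Two numerical details matter:

* **Boundary hygiene.** Median-filtering the depth image (5×5, reflect
  padding, invalid zeros excluded from the window) mixes values across the
  plant/soil boundary. Patches are therefore sampled at a safety margin
  from it: the soil point is chosen at least `margin + 1` px from the
  plant (with `margin` the filter half-width) and soil patches exclude
  plant-labelled pixels, while leaf patches are restricted to the eroded
  plant core. Without this, a soil patch in a notch between leaves reads
  the leaf plane and the noise-free closure property cannot hold.
* **Quantization.** Depth is quantized to 1 mm (noise is applied before
  quantization in the generator, as in real sensor pipelines), so
  noise-free recovery is exact to the quantization step: a 105.8 mm plant
  over a 600 mm soil plane reads 10.60 cm against a true 10.58 cm.

With Gaussian depth noise of σ = 2 mm, the 5×5 filter, the patch median and
the 5 repeats bring the height error under 0.3 cm in effectively all seeded
runs (the suite checks ≥ 95 % over 200 runs).

The camera-to-ground distance $h_1$ does not enter $H$; when supplied
together with the measured box height $b$, the residual $|h_1 - h_2 - b|$
is reported and flagged above 1 cm as a rig-consistency check.

## Canopy temperature (thermal)

The 8-bit gray scale of a thermal frame encodes its calibration span
affinely:

$$T = t_{\min} + \frac{g}{255}\,(t_{\max} - t_{\min}),$$

carried in a JSON sidecar (`<basename>.calib.json`) because PNG carries no
temperature metadata; real radiometric cameras embed the per-frame span,
which the sidecar emulates. The map is strictly monotone, hits both
anchors exactly, and round-trips all 256 levels.

Canopy segmentation offers two methods. **Threshold** (default): the
between-modes valley threshold on the median-filtered gray, taking the
cooler side as canopy (vegetation is cooler than sunlit soil; the side is
a parameter). **Edge**: central-difference gradient magnitude thresholded
at its 90th percentile — floored at a quarter of the maximum so that
sparse but strong step edges keep forming a closed contour — followed by
1-px dilation, hole filling and largest-component selection.

Two deliberate choices:

* Temperature statistics (min, max, mean = sum/count, and the per-pixel
  field) are always computed from the **original** gray values. Equalized
  grays no longer encode temperatures; the suite asserts the statistics
  are unchanged whether or not the enhancement stage ran.
* Histogram equalization is applied **only** for the edge method.
  Equalization flattens the histogram by construction, which destroys the
  very valley the threshold method needs (on a noisy two-mode frame it
  tears the dominant mode into several spurious peaks); being monotone, it
  could not change the thresholded classes anyway.

The mean is robust to the few boundary pixels the smoothed mask may pick
up, but the extremes are not: one soil pixel in the mask shows up directly
in `t_max_c`. Reported means on noise-free synthetic scenes land within
0.2 °C of truth (gray quantization contributes span/255 ≈ 0.12 °C per
pixel at the default 15–45 °C span).

## Agreement statistics

Validation compares systematic (image-derived) with manual measurements per
trait and growth stage: Pearson r with a two-sided p from the exact
t-distribution on n − 2 degrees of freedom (the per-stage samples are
small, so no normal approximation), significance starred at p < 0.05, and
the ordinary least-squares calibration fit `manual = a·systematic + b`
with $R^2 = 1 - SSE/SST$ and $\mathrm{RMSE} = \sqrt{SSE/n}$. The RMSE
denominator is n, not n − 2, because the quantity is read as the deviation
between two measurement routes — a precision metric — rather than a
regression standard error; `rmse_denominator = "n-2"` is available. The
regression direction (systematic on the x-axis) makes the fit a
calibration curve for the rig. Verbal strength labels follow the rubric:
|r| > 0.7 "very strong", 0.4–0.7 "strong", 0.2–0.4 "average", else "weak".
For simple linear regression with intercept, $R^2 = r^2$ to machine
precision, which the suite uses as a cross-check between the two routes.

## The synthetic scene generator

`make_scene()` renders RGB/depth/thermal triplets with exact ground truth:
a round box (200 px ↔ 15 cm by default, i.e. 13.3 px/cm) on a chamber
floor, a rosette of elliptical leaves over a soil matrix, a same-diameter
green reference disk in a separate calibration frame, a depth image (soil
plane with leaf-plane override, noise before 1 mm quantization), and a
thermal gray image obtained by inverting the affine map on the true
temperature field. The px↔cm scale is induced by the rendered reference
disk, so the leaf-area pipeline is tested end to end including
calibration — no separate scale constant leaks into the truth. All
randomness flows from the single scene seed.

Stage presets track the documented growth trajectory: heights
10.58 → 20.0 → 33.28 → 49.28 cm (the pre-tillering value is not reported
and is set midway), canopy temperature rising to late tillering and
falling to 24.39 °C at jointing (unreported stage values chosen once as
28/34/36 °C), with leaf number and size growing by stage. Replicate boxes
within a stage carry deterministic ±10 % leaf-size, ±5 % height and
±0.5 °C spreads, as biological replicates would — without this, noise-free
replicate scenes would be identical and within-stage correlations
degenerate. The floor is rendered at the soil temperature: chamber floor
and soil matrix are thermally similar in practice, and it keeps the
thermal histogram bimodal (canopy vs background), which is the regime the
valley threshold is designed for.

What the generator does **not** emulate: real wheat morphology (leaves are
ellipses — enough to exercise every operator contract, not photorealism),
occlusion, specular soil, emissivity variation, or depth shadowing.
Passing the closure tests therefore shows the extractors are correct
implementations of their models, not that the models survive every field
condition.

Problem sizes used in the tests and the acceptance script — 240² or 160²
px scenes, 200-run noise Monte-Carlos, 4 stages × 3 boxes batches — were
chosen so rasterization error sits well below the stated tolerances while
the whole suite stays fast on one CPU.

## Cruise planning

`s_path()` reproduces the rig's acquisition plan: a boustrophedon
(S-shaped) traversal of the rows × cols site grid (default 6 × 3,
matching the chamber), starting at site (0, 0) along the long axis —
the origin and orientation are configurable since only the S-shape itself
is documented — with 0.5 m/s travel, 50 s dwell per site and 4 frames per
site (midpoint of the documented 3–5). Plans are validated against the
gantry's 6000 × 2000 mm travel envelope. Site spacing is not documented
and is a required parameter.

## Degenerate inputs and tie-breaks

* Valley thresholding smooths the 256-bin histogram with a centred moving
  average (window 9), takes the two highest local maxima at least 10 gray
  levels apart whose intervening minimum drops below 0.8 of the lower
  peak (an "obvious" valley; wiggles on one broad mode are rejected), and
  thresholds at the valley minimum — midpoint of a flat plateau. Unimodal
  or constant histograms fall back to Otsu's criterion, flagged in the
  result. Otsu ties break to the lowest gray level; an all-one-level
  histogram returns that level with a degenerate flag.
* Median filters require odd kernels ≥ 3 and use reflect padding; for
  depth, invalid zeros are excluded from the window and an all-invalid
  window yields 0.
* Connected components default to 8-connectivity (thin leaves survive
  8-connectivity better); small-object removal keeps components at exactly
  `min_area_px` and is idempotent and monotone in the threshold.
* An empty plant mask degenerates the soil-center rule to the box
  centroid; a plant filling the box is a detection error. A leaf reading
  below the soil surface returns the negative height with a `below_soil`
  flag rather than failing, since that is a recognizable sensor-noise
  signature.

## Known limitations

* Circularity-based reference detection assumes the reference is the only
  compact round green object in frame; a compact round weed would be
  picked if it also matched the expected area window.
* The leaf count is a vertical projection: overlapping leaves are counted
  once, so the trait is projected canopy area, not total blade area — the
  same bias the reference-disk method has on the real rig.
* Thermal extremes (`t_min_c`, `t_max_c`) are sensitive to single
  mis-segmented boundary pixels; the mean is the robust summary.
* The depth pipeline assumes pre-registered RGB-D frames (identity
  alignment); arbitrary per-pixel maps are supported but not estimated.
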