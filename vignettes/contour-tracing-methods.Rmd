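---
title: "Bi-planar optical contour tracing: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-planar optical contour tracing: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oact)
```

## The measurement problem

A custom electron cutout must reproduce, at the cutout plane (typically
95 cm from the source), a contour drawn on the patient's skin. The skin
is neither flat nor at a fixed distance from the source, so a single
photograph cannot recover the contour's true shape: the magnification of
each point depends on its unknown depth. This package solves that with two
photographs taken by the same camera at two known heights `h1` and `h2`
above the isocenter plane, both looking straight down the beam central
axis. For each contour point the pair of pinhole projections
over-determines its depth, and the closed-form relations

$$x = \frac{x_1 x_2 (h_1-h_2)}{d\,(x_2-x_1)},\qquad
  z = \frac{x_1 h_1 - x_2 h_2}{x_2-x_1}$$

(and the $y$ analogues) recover the 3D coordinates without any knowledge
of the skin surface. The cutout coordinate then follows from the
per-point magnification $b/(\mathrm{SSD}+z)$.

### Assumptions

* The two views are **coaxial**: the camera is translated along the beam
  axis between exposures (mounted on two applicator scraper levels), with
  no rotation between views. Mount misalignment is not modeled.
* Inputs are **distortion-corrected**. A single-coefficient radial
  correction (`k1`, applied to normalized image coordinates before
  reconstruction) is available for lens residuals but defaults to off.
* The drawn contour is **star-convex** about its geometric center: every
  ray from the center crosses the stroke once. This is inherent to the
  radial parameterization; violations are detected and reported, not
  silently accepted.
* Heights are measured to the camera **optic origin** (the pinhole), and
  `d` is the optic-to-imaging-plane distance, so `N = D·d/(h+z)` holds
  exactly in the pinhole model.

## Parameters that matter

| parameter | units | default | role |
|---|---|---|---|
| `h1`, `h2` | cm | 40, 60 | camera heights above the isocenter plane; any distinct pair below the SSD works, wider separation improves depth conditioning |
| `d` | cm | 0.368 | optic-to-imaging-plane distance; sets image scale |
| `pixel_pitch` | cm/px | 2.268e-4 | physical pixel size; the only pixel-to-cm bridge |
| `ssd` | cm | 100 | source-to-surface reference; defines the isocenter plane |
| `b` | cm | 95 | source-to-cutout distance; flat contours scale by `b/ssd` |
| `interval_deg` | degrees | 5 (N = 72) | radial sampling step; 1° (N = 360) for intricate shapes |
| `sigma` | px | 2 | Gaussian smoothing before binarization |

All geometry is carried in cm internally; pixels are converted to cm once,
at the imaging/geometry boundary, using `pixel_pitch`.

## Numerical choices

* **Depth from two axes.** The closed form gives one depth estimate per
  axis; under pixel noise they disagree. `reconstruct_point()` averages
  them weighted by the projection disparities `|x2−x1|` and `|y2−y1|`,
  which discounts the axis with the poorer signal-to-noise. When one
  disparity falls below the degeneracy tolerance (1e−6 cm, far below a
  pixel pitch) the other axis alone supplies `z` and the degenerate
  coordinate is recovered from `N·(h+z)/d`. Points degenerate on both
  axes (on the optical axis) are interpolated over angle from their
  neighbors; more than 25% such points aborts the reconstruction.
* **Binarization** uses Otsu's threshold on the smoothed ROI. It is
  parameter-free and adapts to exposure and skin tone, which is exactly
  what a clinical deployment needs; no manual threshold is exposed.
* **Skeletonization** is Zhang–Suen thinning to an 8-connected unit-width
  centerline, followed by pruning of spurs shorter than 5 px (endpoint
  stripping, which cannot damage a closed cycle). No installed package
  provides thinning, so it is implemented here directly.
* **Radial sampling** uses the median center-to-pixel distance within
  each angular bin rather than a literal ray–pixel intersection:
  rasterized skeletons make exact ray hits unreliable, while the bin
  median is its stable equivalent. Empty bins are filled by circular
  linear interpolation over angle; more than 50% empty bins is an error.
  A bin whose pixel radii spread over more than 20% of the bin median
  indicates a star-convexity violation and raises a warning.
* **Metric resampling** (`align_for_cmi()`) is exact: each polygon is
  translated to its area centroid and intersected with rays on the shared
  angle grid, on the polygon edges, with duplicate hits at shared
  vertices collapsed. Alignment is translation-only — no rotation or
  scale registration — because the clinical comparison lives in a fixed
  beam's-eye-view frame, and registering away a systematic shift would
  hide a real delivery error.
* **CMI uses |Δr|.** The index is defined with the absolute radial
  deviation; a signed version could exceed 1 or reward cancellation,
  defeating its purpose as the cancellation-proof complement to the ARI.
* **Summary convention.** Tabulated index summaries use the population
  standard deviation (divisor N). Percentage differences between matched
  series are `100·(a−b)/b` with the second-named series as baseline.

## The simplified mean-scaling mode

An alternative single-formula mode computes
`x_new = ((h1+h2)/d_sc)·((x1+x2)/2)`. This is *not* equivalent to the
exact reconstruction: equating the two for a flat contour shows the
scaling constant must be
`d_sc = d·(h1+h2)²/(2·h1·h2)·(SSD/b)` (`averaged_scaling_constant()`),
and even then the agreement holds only at `z = 0`. The mode is provided
for comparison and calibration studies; the exact route is the default
everywhere.

## What the synthetic generator emulates — and what it does not

`make_shape()` + `render_pair()` stand in for the photographed test
objects: a closed star-convex curve (circle, ellipse, or a band-limited
Fourier blob with up to six harmonics, standing in for irregular organic
shapes) draped on a flat, tilted-plane or spherical-cap surface, projected
through the same pinhole model the reconstruction inverts, and rasterized
as an anti-aliased dark stroke (sub-pixel curve sampling at four samples
per pixel) with seeded additive Gaussian noise.

The default study conditions mirror the physical rig: a 2720 × 2040 frame
(1/2.3-inch 5 MP sensor, 6.17 mm across, hence a 2.268e-4 cm pixel pitch
and `d = 0.368` cm for an ~80° field of view), heights 40 and 60 cm, a
3 px stroke, stroke/background intensities 0.1/0.95 and noise SD 0.02.

The generator does **not** emulate: shadows or specular highlights,
colored marker ink on textured skin, lens distortion, sensor effects
(Bayer mosaics, rolling shutter), or camera mount misalignment. Passing
the synthetic suite therefore demonstrates the geometry, image-processing
chain and metrics are correct under controlled optics; it does not certify
segmentation robustness on arbitrary clinical photographs, where the crop
box and lighting are the user's responsibility and the QC overlays should
be inspected.

## Problem sizes used in the shipped validation

The test suite renders full-resolution (2720 × 2040) scenes for the two
headline recovery cases — a flat 3 cm circle and a blob on a tilted plane
with depth spanning beyond ±2 cm — and reduced-resolution frames (the same
field of view at 1/2 to 1/8 the pixel count) for property sweeps such as
noise robustness and the resolution-monotonicity check; the geometry
round-trip property uses 10⁴ random points. These sizes make the whole
suite run in well under a minute while keeping the headline cases at the
camera's native resolution.

With those conditions the flat circle is recovered with ARI within 1% of
unity and CMI above 0.98, and the tilted-surface blob with CMI above 0.97
— the depth-varying case is the one that actually exercises the per-point
magnification, and collapsing it to a single average magnification would
fail it.

## Known limitations

* Non-star-convex contours cannot be represented by the radial
  parameterization at all; the package refuses them rather than
  returning a silently wrong cutout.
* The two radial contours are corresponded by angular index about each
  image's own center. For a shape whose center shifts strongly off-axis
  between the two views this correspondence is approximate; keeping the
  lesion near the beam axis (standard clinical practice) keeps the error
  negligible.
* `z` accuracy degrades as `h1 → h2` (disparity vanishes); the scraper
  separation of the defaults (20 cm) is comfortable.
* Exact reproduction of published per-shape CMI values for hand-drawn and
  CT-based tracings would require the original photographs; the shipped
  validation instead proves the metric implementations on analytic
  fixtures and the full pipeline on synthetic scenes.
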