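---
title: "Shagginess scoring: model, pipeline, and validation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shagginess scoring: model, pipeline, and validation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The score

Atheromatous degeneration roughens the aortic lumen. On a cross-section
perpendicular to the vessel axis, roughness lengthens the luminal contour
without a proportional change in caliber, so the ratio of contour length to
the circumference of an equivalent circle isolates shape irregularity from
size. Concretely, per slice:

* `A` — contour length of the traced lumen boundary (mm);
* `B` — mean of `n_angles = 180` diameters through the centerline point,
  one per degree, each diameter the sum of the two opposed ray-to-wall
  distances;
* `C = A / (π B)`, and the slice irregularity `(C − 1) × 100`.

The score of a vessel segment is the unweighted arithmetic mean of the slice
irregularities over an inclusive, landmark-delimited arc-length range. Slices
are taken at a regular spacing (default 1.5 mm, within the conventional
1.2–1.7 mm band), so the plain mean is equivalent to arc-length weighting.
Slices where measurement fails carry flags (`no_contour`,
`centroid_fallback`, `fan_failed`) and are excluded from the mean but always
reported, so every exclusion is auditable.

For a circle C = 1 exactly. For a convex section measured through an interior
point C ≥ 1, with the excess growing quadratically in wall undulation: for a
lobed wall `r(θ) = R (1 + ε sin kθ)` the small-amplitude expansion gives
`C ≈ 1 + k²ε²/4`. C is dimensionless and invariant under uniform scaling, so
the score reflects shape, not caliber.

`π` is used at full machine precision by default. Workstation displays often
print the two-decimal shorthand `3.14`; `circularity_ratio(..., pi_value =
3.14)` replicates that convention exactly (it changes C by about 0.05%, far
below other error sources).

## Pipeline

1. **Input** (`read_volume`): NIfTI volumes, world geometry from the
   sform/qform affine in mm. For attenuation input (`kind = "ct"`), a
   threshold (default 200 HU) plus seeded connected-component selection
   yields the lumen mask.
2. **Centerline** (`extract_centerline`): minimum-cost path between two
   user-supplied seed points on the 26-connected foreground voxel graph.
   A step of length `ds` between voxels `a`, `b` costs
   `ds · (c(a) + c(b))/2` with `c(v) = 1/(1 + DT(v))²`, where `DT` is the
   exact Euclidean distance transform in mm — the standard medialness
   weighting that pulls the path onto the locus of maximal inscribed spheres.
3. **Regularization** (`smooth_and_resample`): moving-average smoothing
   (default 10 mm window — wide enough to kill voxel-scale zig-zag that
   would corrupt plane normals, narrow enough to preserve aortic-scale
   curvature), then resampling at the slice spacing.
4. **Sub-voxel refinement** (`refine_centerline`, 2 passes by default): a
   voxel-graph path can only pass through voxel centers, so even after
   smoothing it may ride a constant half-voxel off the true luminal center.
   A systematic center offset δ biases the mean diameter low by order
   `δ²/(4R²)` and therefore inflates C. Each pass re-centers every point on
   the area centroid of its own perpendicular contour; on straight-tube
   phantoms this reduces the axis offset from ~0.7 voxel to a few hundredths.
5. **Frames** (`plane_frames`): plane normals are the tangents; in-plane
   axes are propagated by rotation-minimizing (parallel-transport) frames so
   consecutive slices do not spin.
6. **Slice measurement** (`measure_slice`): the volume is resampled on each
   plane (default grid: ±40 mm at 0.5 mm), the lumen contour is traced as
   the sub-pixel marching-squares iso-contour (level 0.5 for masks, the HU
   threshold for attenuation input) enclosing the centerline point, oriented
   CCW and resampled to 720 equally spaced vertices; then A, the 180-ray
   diameter fan, and C.
7. **Aggregation** (`shagginess_score`): mean over in-range, unflagged
   slices; the result object carries the full per-slice tibble and the
   complete settings record.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `slice_spacing_mm` | 1.5 | mm | cross-section spacing; 1.2–1.7 conventional |
| `n_angles` | 180 | — | diameters per slice (1° steps via paired rays) |
| `n_vertices` | 720 | — | contour vertices after resampling |
| `half_extent_mm` | 40 | mm | in-plane field of view half-width |
| `grid_spacing_mm` | 0.5 | mm | in-plane sample spacing (0.25 for oracle-grade accuracy) |
| `level` | 0.5 | — | iso-level for mask input; HU threshold for CT input |
| `smooth_window_mm` | 10 | mm | centerline moving-average window |
| `refine_iterations` | 2 | — | centroid re-centering passes |
| `crossing` | "first" | — | ray-crossing policy on non-convex contours |

The fixed 720-vertex resampling addresses the "coastline" problem: the
perimeter of a polygonal trace depends on its vertex density, so fixing the
count makes A comparable across inputs. Resampling places vertices equally
spaced *along the input polyline*; corners falling between sample points are
cut, shortening the perimeter by at most ~(κ·Δs)²/24 per segment — below
10⁻⁴ relative for aortic-scale contours.

For non-convex contours the "first" (nearest) ray-crossing is the default:
plaque protruding into the lumen then narrows the measured diameter, which is
the phenomenon the score should sense. The "farthest" policy is available
for sensitivity analyses. When the centerline point falls outside the traced
contour (crescent-shaped lumen), the fan center falls back to the contour
centroid and the slice is flagged `centroid_fallback`.

## Numerical choices

* **Volume interpolation** is separable Catmull-Rom cubic by default.
  Trilinear interpolation of a 1 mm-voxel field attenuates wall undulations
  at ~10 mm wavelength by a few percent; because the score grows as ε², that
  produced a ~4% score deficit on strongly lobed phantoms. Cubic convolution
  is exact for locally linear fields and nearly flat in the relevant
  pass-band; `interpolation = "linear"` remains available.
* **Iso-contour extraction** uses marching squares with linear interpolation
  (`grDevices::contourLines`). When samples tie the level *exactly* —
  guaranteed with strictly binary masks — marching squares emits broken
  fragments; the level is then nudged by 10⁻⁷ of the value range, a
  deterministic tie-break that does not measurably move the contour.
* **Ray–edge intersection** accepts edge parameters in `[−10⁻⁹, 1 + 10⁻⁹)`
  so a ray passing exactly through a polygon vertex cannot fall between the
  two adjacent half-open edge ranges. Residual fan failures (none observed
  after this fix) would flag the slice rather than abort the run.
* **Determinism**: the scoring path contains no randomness; identical input
  and configuration reproduce the per-slice CSV byte for byte.

## The phantom generator

`phantom_spec` + `rasterize_phantom` build tubes with star-shaped polar
cross-sections `r(θ)` (circle, ellipse, lobed, Gaussian-bumped) swept along
straight, circular-arc, or helical paths, with an optional rigid pose. The
star-shape restriction is deliberate: it makes the through-center chord
`d(θ) = r(θ) + r(θ + π)` well-posed under the first-crossing policy and turns
the ground truth into one-dimensional quadrature. `analytic_section` computes
A by arc-length quadrature and B by chord quadrature with the periodic
trapezoid rule at 16,384 nodes, which converges spectrally for these smooth
periodic integrands (residual ≪ 10⁻⁸).

Rasterization emulates partial volume with a clamped signed-distance ramp one
voxel wide (`value = clip(0.5 + d/(2h))`), optionally followed by a Gaussian
blur (`blur_sigma_mm`) as a crude point-spread stand-in. The ramp keeps the
0.5 level set of the interpolated field on the true boundary to second order
in curvature, so the oracle comparison probes the pipeline rather than the
rasterizer. Re-binarizing after blurring would discard exactly this sub-voxel
information, which is why the field is emitted as fractional occupancy
(`antialias = FALSE` gives a strict binary volume for robustness tests). The
grid origin is offset half a voxel so voxel centers sit at generic positions
relative to the tube axis, as in real scans.

Phantom defaults mirror the acquisition they emulate: 1 mm isotropic voxels
(typical arterial-phase CT slice thickness), tube radii 8–12.5 mm (aortic
caliber), lengths 60–150 mm. Scoring landmarks suggested by the generator are
inset from the tube ends (≥10 mm or ~1.6 R) because slices near the open end
caps see the cap, not the wall.

## Validation problem sizes and what they show

The test suite and `scripts/acceptance.R` validate on: a circular tube
(R = 12.5 mm, 150 mm long; score magnitude < 0.5, decreasing with in-plane
refinement from 0.5 to 0.25 mm), an elliptical tube (15 × 10 mm semi-axes;
pipeline within 5% of the quadrature irregularity 4.145), lobed tubes
(`r = 10(1 + ε sin 6θ)`, ε ∈ {0.02, 0.05, 0.10}; each within 2% of
quadrature truth and strictly increasing), rigid-rotation (30° about an
oblique axis) and uniform ×2-scaling invariance (< 1% score change),
centerline recovery on straight and 90°-arc tubes (< 1 voxel RMS), agreement
of the vectorized geometry with an exhaustive scalar ray-casting oracle on 50
random star polygons (< 10⁻⁶ relative), and byte-identical repeated runs.

These phantoms establish *geometric correctness*, not clinical equivalence.
Real CT adds noise, motion, contrast-timing gradients, branch ostia that open
the luminal contour, and a proprietary tracing step on the workstation side;
none of these are simulated. Absolute scores are therefore
pipeline-dependent, and cohort thresholds from one implementation should not
be transplanted onto another without recalibration. Branch-ostium slices are
scored as-is (or fail loudly and get flagged); restricting the landmark range
is the supported mitigation.

## Known limitations

* Input is NIfTI only; DICOM series should be converted upstream.
* Bifurcation-aware centerline trees and lumen segmentation from
  unthresholdable CT are out of scope.
* The mean-diameter center follows the refined central luminal line; for
  strongly eccentric (crescent) lumens the centroid fallback changes the fan
  origin, and such slices are flagged so users can inspect or exclude them.
* The score does not separate diffuse wall roughness from a single large
  ulcer at equal contour excess; it is a summary index, not a lesion
  detector.
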