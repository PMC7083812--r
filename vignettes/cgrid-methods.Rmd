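---
title: "Grid normalization of the sensorimotor cortex: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid normalization of the sensorimotor cortex: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`cgrid` maps the sensorimotor strip of a flattened cortical hemisphere onto
a fixed N×M Cartesian grid. The core assumption is *proportional
somatotopy*: even when the absolute position of a functional hotspot
differs between subjects (or between a subject's hemispheres), its position
relative to the dimensions of the sensorimotor cortex is preserved. Under
that assumption, dividing each individual strip into the same number of
tiles along its own anatomical axes brings homologous locations into
register, without any volumetric or spherical registration, and makes left
and right hemispheres directly comparable.

The construction, given a labeled flat mesh:

1. **Borders.** A border is the set of vertices of one atlas label with at
   least one mesh neighbor of another label. Three vertical borders
   (precentral sulcus, central sulcus, postcentral sulcus) and two
   horizontal ones (dorsal: vs paracentral lobule; ventral: vs insula)
   bound the strip. If a border splits into several connected components
   (label islands occur in real parcellations), only the largest is kept,
   with a warning — a stray island would corrupt the polynomial fit.
2. **Fits.** An order-10 polynomial `x(y)` is least-squares fitted through
   each vertical border, treating the dorsoventral coordinate as the
   independent variable. Order 10 captures sulcal shape while still
   extrapolating stably over the short distances required.
3. **Interpolation.** M+1 vertical curves are obtained by linearly
   interpolating the 11 coefficients — precentral→central over columns
   0..M/2, central→postcentral over M/2..M — so the central sulcus is
   pinned at the middle column and M1/S1 are exactly the grid halves. Each
   curve is evaluated in unit (1 a.u.) steps from `y_min` (ventral border
   minimum) to `y_max` (dorsal border maximum).
4. **Truncation and resampling.** Each curve is cut at the nodes nearest
   (Euclidean) to the ventral and dorsal borders, then resampled into N
   segments of equal arc length, giving an (M+1)×(N+1) node lattice and
   N×M quadrilateral tiles.
5. **Mapping.** Each vertex is assigned to the tile enclosing it; a tile's
   value is the unweighted mean of its member vertices' field values.
   Tiles without sensorimotor vertices are masked invalid and excluded
   from every correlation.

Similarity between two maps is the Pearson correlation over tiles valid in
both, Fisher z-transformed (`arctanh`) for averaging and testing, and
converted back with `tanh` for reporting. Aggregation always averages z,
never r.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `N` (rows) | 28 | tiles | dorsoventral resolution |
| `M` (columns) | 84 | tiles | anteroposterior resolution; must be even so the central sulcus is a column boundary |
| polynomial order | 10 | — | border shape flexibility vs extrapolation stability |
| curve sampling step | 1 | a.u. | lattice on which interpolated polynomials are evaluated |
| arc densification step | 0.1 | a.u. | nominal node spacing for arc-length estimation |
| smoothing `fwhm` | 6 | a.u. | surface smoothing of vertex fields before mapping (1 a.u. ≈ 1 mm on typical flat maps) |
| r clamp | 1 − 1e−7 | — | keeps `arctanh` finite on perfectly correlated synthetic patterns |

Both grid dimensions are configurable; the defaults give tiles of roughly
3 a.u.² on a typical adult sensorimotor strip with about six vertices per
tile.

## Numerical choices

* **Fit conditioning.** Order-10 monomial fits on raw coordinates in the
  tens-to-hundreds are numerically singular; fits are computed on a
  centered, scaled ordinate `t = (y − c)/h` mapped to roughly [−1, 1].
  Because coefficient interpolation across the three fits is only
  meaningful in a shared basis, the three fits are re-expressed exactly
  (affine change of variable on the polynomial) in a common basis spanning
  `[y_min, y_max]` before interpolation.
* **Extrapolation guard.** Curves extrapolate the border fits up to
  `y_min`/`y_max`; if an interpolated curve ever exceeds three times the
  mesh's x-extent the build aborts with a geometry error rather than
  producing a folded grid.
* **Equal-arc resampling.** The truncated curve is a polyline; densifying
  a polyline to 0.1 a.u. node spacing changes neither its summed length
  nor positions interpolated along it, so the resampler places the N+1
  nodes by exact linear interpolation of cumulative arc length, with the
  endpoints preserved bit-exactly.
* **Tile assignment.** Point-in-polygon uses the even-odd rule with no
  convexity assumption (strongly curved borders can make tiles
  non-convex). Vertices exactly on a shared edge are deterministic: tiles
  are tested in row-major order and the first containing tile — the
  lexicographically smallest (row, column) — wins; a vertex is never
  assigned twice. Vertices enclosed by no tile stay unassigned; a warning
  fires if that affects more than 10% of the region's vertices.
* **Orientation.** Map matrices are stored in display convention (dorsal
  top, columns in flat-map x order). Which hemisphere needs a column flip
  to put the precentral sulcus on the left depends on the flattening
  tool's handedness, so `orientGrid()` takes an explicit convention flag
  (`"caret"`: the right hemisphere is mirrored) instead of guessing.
  Orientation is idempotent.
* **Smoothing.** Surface smoothing is iterative relaxation towards the
  cotangent-weighted neighbor mean — the standard isotropic
  discretization of surface diffusion; uniform edge weights would bias
  diffusion along the dominant triangulation diagonal. Step count and
  relaxation weight are calibrated from the weighted mean squared neighbor
  displacement so the accumulated per-axis variance matches the requested
  Gaussian, which the impulse-response tests verify to within 15%. Missing
  values are handled by normalized convolution. The kernel width is
  specified in flat-map a.u.; on real data smoothing in a.u. only
  approximates a millimetric kernel on the folded surface, and no exact
  equivalence is claimed.
* **Degenerate inputs.** Empty borders, underdetermined or rank-deficient
  fits, degenerate dorsoventral ranges, zero-length curves, fewer than 3
  jointly valid tiles, and zero-variance inputs to the correlation or the
  paired t-test all raise distinct, named error conditions.

## The synthetic generator

`makeSubjectFlatmap()` builds a band-shaped two-gyrus region on a
parametric rectangle (s anteroposterior, t dorsoventral), surrounded by
the eight neighbor labels in anatomically correct positions, triangulated
at a target edge length and pushed through a smooth random warp: low-order
harmonic displacements (band bending across t, milder shear along s) drawn
deterministically from the seed. Warps are deliberately non-affine so that
grid normalization is exercised on exactly the kind of shape variability
volumetric registration does not remove; a warp strong enough to fold the
band is rejected with advice to lower its amplitude. Defaults — a 60 × 120
a.u. band, 0.7 a.u. vertex spacing (≈6 vertices per default tile), 5 a.u.
warp amplitude — approximate a real adult sensorimotor strip.

`makeActivation()` plants isotropic Gaussian hotspots *in parametric
coordinates* plus white noise; `taskHotspots()` supplies the canonical
somatotopy (feet t = 0.90, hand t = 0.67, tongue t = 0.15, all centered on
the central sulcus at s = 0.5, hand tasks predominantly contralateral with
a 4:1 amplitude ratio). `makeCohort()` generates per subject two
independently warped hemispheres (the right mirrored in x) and the four
task fields; hotspot positions can be jittered per subject, or scrambled
uniformly as a negative control that destroys the shared somatotopy.
Every vertex's true parametric position is stored in the mesh metadata for
oracle use only — the grid pipeline never reads it.

What the generator does *not* emulate: realistic fMRI noise spectra and
hemodynamics, GLM estimation, distance distortions introduced by actual
flattening, parcellation errors beyond simple label islands, and
individually complex multi-focal activation patterns. Passing tests
therefore demonstrate the correctness and stability of the transform and
statistics under controlled anatomical variability, not performance on
real data.

## Design decisions

* The three-fit interpolation pins the central sulcus at column M/2 with
  piecewise-linear coefficient blending on each side, which makes the
  M1/S1 halves exact column blocks of the oriented grid.
* N counts dorsoventral segments (rows) and M anteroposterior columns;
  both are configurable and the defaults are 28 × 84.
* Borders are stored as unordered vertex sets; ordering along y is a
  fitting concern, not a border concern.
* Tile means are unweighted over vertices; weighting by vertex count is a
  conceivable variant but is not the default behavior anywhere.
* Leave-one-out mean maps use tiles valid in *all* contributing subjects;
  pairwise comparisons intersect the two masks.
* Truncation happens on the unit-step curve, with arc length then computed
  on the (conceptually densified) truncated polyline.
* Coordinates stay in the source's arbitrary units throughout; nothing is
  rescaled to millimetres.
* Flat maps exported from 3D tools are accepted only when `max |z|` is
  below 1e−6 of the xy extent; silently projecting a curved surface would
  corrupt distances.

## Problem sizes used by the test suite

Unit and property tests run on coarse synthetic subjects (≈3k vertices,
14 × 28 grids) so that brute-force oracles — exhaustive neighbor scans,
independent point-in-polygon assignment, hand-rolled leave-one-out loops,
numerical integration of the t density — stay exact and fast. The
end-to-end checks use full-sized subjects (≈23k vertices, 28 × 84 grids):
planted-hotspot recovery over 20 seeds and a 10-subject cohort evaluated
at 6 a.u. smoothing, together with a hotspot-scrambled negative control.
These sizes were chosen as the smallest at which the full-scale geometry
(tile area, vertices per tile, warp amplitude relative to band size)
matches a realistic strip.

## Known limitations

* The transform presumes a band-like region with five well-defined
  borders; compromised gyral integrity (atrophy, lesions) may require
  manual intervention, which is out of scope here.
* Areal and metric distortion introduced by flattening is inherited, not
  corrected; equal arc length on the flat map is not exactly equal
  geodesic length on the folded surface.
* Tiles at the grid edge can be empty at realistic mesh resolutions; they
  are masked rather than filled.
* The correlation uses the whole grid pattern, so it is sensitive to
  activity outside the task's primary representation (a property, not a
  bug, of whole-pattern similarity).
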