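---
title: "Local Z projection and deprojection morphometrics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local Z projection and deprojection morphometrics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiproj)
```

## The problem

Confocal and light-sheet stacks of epithelia image a thin, curved cell
layer embedded in a volume that usually contains other fluorescent
structures — in the fly notum, an auto-fluorescent cuticle a few
micrometres apical of the junctional plane and bright fat bodies below it.
Two distinct artifacts follow:

1. **Projection contamination.** The maximum intensity projection (MIP)
   takes the brightest voxel along each z column, so any bright structure
   in any layer leaks into the 2D image and degrades segmentation.
2. **Geometric foreshortening.** Even a perfect projection maps a tilted
   or curved tissue onto the XY plane. A planar cell whose apical plane
   makes an angle $\theta$ with XY has its area scaled by $\cos\theta$,
   so the relative error of a 2D area measurement is exactly
   $e_a = 1 - \cos\theta$; at $\theta = 60^\circ$ that is a 50% error.

`epiproj` addresses both: a *local* Z projection that collects intensity
only around a reference surface, and a *deprojection* step that lifts a 2D
segmentation back onto that surface and measures morphology in 3D.

## The reference surface (height-map)

The tissue is assumed single-valued in z: one surface position $z_t =
f(x, y)$ per pixel (folded epithelia are out of scope). The discrete form
is the *height-map*. Extraction works per z plane:

1. optional block **binning** by the mean (factor $b$), which suppresses
   pixel noise and reduces cost;
2. optional **Gaussian pre-smoothing** (`presmooth_sigma`, binned pixels);
3. a 2D **response filter** — windowed mean or windowed population
   standard deviation over a `filter_window` square with symmetric
   (reflective) border padding. The std filter responds to the textured
   junctional lattice; the mean filter to bright sheets.

Per binned pixel the height-map is the $z$ maximising the response, ties
broken toward the smallest $z$ (the slice closest to the objective). The
argmax map is then regularised with a large **median filter** (again in
binned space, where it is cheapest and the outliers live), which rejects
localised wrong maxima such as fat-body spots, and finally rescaled to the
full image extent by bilinear interpolation between block centres — so
height-map values are real-valued, and downstream code never assumes
integers.

Defaults (`height_map_params()`): std filter, window 21, binning 2, no
pre-smoothing, median window 21. These suit notum-like volumes. For steep
surfaces the window footprint matters: on a $60^\circ$ slope a 42-px
footprint spans ~11 slices of surface travel and blurs the argmax. A
useful rule is to keep `filter_window * dx * tan(theta_max)` below two or
three slice spacings; the planar-fixture analyses in the tests use window
9 with binning 1 for exactly that reason.

## Local projection

For each channel, with $z^* = \mathrm{round}(f(x,y))$ (half-up), intensity
is accumulated over slices $z^* + \mathrm{offset} \pm \Delta z$, clipped
to the stack; the per-channel `offset` collects e.g. a nuclear reporter a
few micrometres below the junctional surface. Accumulation is `max` or
`mean`; the mean divides by the number of slices actually used after
clipping, and a window that falls entirely outside the stack collapses to
the nearest valid slice. With $\Delta z$ spanning the whole stack, `max`
mode degenerates to the MIP (a test asserts this).

`project_stack()` is a strict two-pass pipeline: pass one reads the target
channel to build the height-map, pass two reads each channel once to
project. On a streamed stack (plane-on-demand reader, one plane resident
at a time) no plane is therefore read more than twice; the stack object
counts accesses so the contract is verifiable, and timepoints are
processed independently with per-timepoint height-maps.

## Deprojection

The height-map is smoothed with a Gaussian of $\sigma$ equal to the median
cell diameter (by default estimated from the mask as the median
equivalent-area diameter) to suppress the staircase left by integer slice
positions, converted to micrometres, and exposed as a bilinear interpolant
$f$. Cell polygons are traced from the label mask at the 0.5 iso-level
(sub-pixel, midway between region and background pixel centres; binary
junction masks are first component-labelled). Each vertex $(x, y)$ lifts
to $(x, y, f(x, y))$.

Per cell the package reports: 2D and 3D area and perimeter and the
relative errors $e_a = 1 - a_{2D}/a_{3D}$, $e_l = 1 - l_{2D}/l_{3D}$; the
total-least-squares apical plane (normal, slope $\theta =
\arccos|n_z|$, Euler angles in the Z-X'-Z'' convention); the
moment-equivalent ellipse measured *in the apical plane* (semi-axes,
orientation, eccentricity) and, separately, on the XY projection — the
field is ambiguous about which frame "orientation" refers to, so both are
emitted under distinct names; neighbour counts (regions touching within a
2-px dilation); and the local surface curvatures at the cell centroid.

### 3D polygon area

Pixel-traced contours are locally concave (one-pixel notches along the
junction band), which forced a deliberate choice. A centroid fan summed as
*unsigned* triangle magnitudes is exact only for star-shaped contours and
overestimates the area of digitised polygons by 1–2%, which would break
the planar law $e_a = 1-\cos\theta$ at the precision it actually holds.
The package therefore sums the centroid-fan triangles with a *consistent
orientation* (each triangle signed by its cross product against the
contour's total vector area). This is exact for every planar simple
polygon, coincides with the unsigned fan on star-shaped contours, and
still responds to out-of-plane deformation (which the perturbation
procedure relies on). Consequences verified by tests: on a flat surface
every 3D metric equals its 2D counterpart exactly, planar cells obey
$e_a = 1-\cos\theta$ to machine precision, and $a_{3D} \ge a_{2D}$ holds
(the projection of any contour can only shrink).

### Curvature

With the Monge patch $z = f(x,y)$, mean and Gaussian curvature are
computed from central finite differences of the smoothed height-field:

$$H = -\frac{(1+f_y^2)f_{xx} - 2 f_x f_y f_{xy} + (1+f_x^2)f_{yy}}
{2\,(1+f_x^2+f_y^2)^{3/2}},
\qquad
K = \frac{f_{xx}f_{yy} - f_{xy}^2}{(1+f_x^2+f_y^2)^2}.$$

The sign is chosen so that domes (local maxima in z, tissue bulging away
from the objective) have $H > 0$; $K$ is sign-independent of that choice.
A sphere of radius $R$ gives $H = 1/R$, $K = 1/R^2$; a cylinder
$H = 1/(2R)$, $K = 0$. Derivative grids are computed once on the smoothed
map and interpolated at cell centroids; near image borders one-sided
differences apply, and — more importantly — Gaussian smoothing with
reflective padding creases the surface wherever a sloped surface meets the
border or a rim kink. Curvature estimates are therefore only trusted for
cells whose full smoothing support is interior; the tests exclude cells
within $2\sigma$–$3\sigma$ of rims and borders, and the same caveat
applies to real tissue edges.

### Height-map sensitivity

To probe how a locally wrong height-map propagates into the measurements,
`perturb_contours()` moves half of each cell's contour vertices up by one
z step and recomputes $a_{3D}$ and $l_{3D}$. The moved half is a
contiguous boundary arc with a uniformly random, seeded start
(`vertices = "block"`): a locally erroneous height-map deforms one side of
a cell coherently. The alternative reading — a scattered random half
(`vertices = "random"`) — is also implemented, but with pixel-dense
contours (vertex spacing of a fraction of the z step) it makes nearly
every edge jump by the full step, inflating the 3D perimeter by tens of
percent; that zig-zag models per-vertex noise rather than height-map
error, and its magnitude is inconsistent with the few-percent sensitivity
this procedure is meant to quantify. On the bump fixture the block
procedure yields mean errors of a few percent on area and perimeter —
non-zero, seed-reproducible, and well below the $e_a$ distortion the
deprojection corrects for steep cells.

## The synthetic fixtures

Every quantitative claim in the tests is made on generated data with known
ground truth (`synthetic_preset()` / `synthetic_fixture()`); each fixture
ships its analytic surface, sampled height-map, label mask and ideal
projection, and a seed fully determines every voxel.

* Surfaces: flat, tilted plane, Gaussian bump, spherical cap
  ($R = 50\,\mu m$, $h = 10\,\mu m$), cylinder ($R = 50\,\mu m$); all
  constrained to stay inside slices $[2, n_z - 1]$.
* Cell lattice: Poisson-disc-sampled seeds (dart throwing; the exclusion
  radius relaxes deterministically until the requested count fits, giving
  epithelium-like regularity) tessellated by nearest-seed assignment into
  convex cells separated by a 1-px junction band.
* Rendering: the junctional lattice is painted at the surface with a
  realistic axial extent (the `notum` preset uses 3 slices ≈ 2 µm — an
  infinitely thin membrane would all but vanish under the axial PSF), plus
  optionally a diffuse junctional-plane fill, an auto-fluorescent textured
  cuticle sheet a few slices apical, bright fat-body spheres below,
  separable Gaussian PSF blur with $\sigma_z \ge 2\sigma_{xy}$ (the axial
  elongation of confocal optics), a constant camera baseline, and Gaussian
  or Poisson noise last. The `notum` preset's stated SNR ≈ 3 is the
  post-PSF membrane amplitude over the noise sd.
* The *ideal projection* is defined as the noiseless (but blurred) volume
  sampled at the true surface — the image a perfect height-map would
  collect with offset 0 and $\Delta z = 0$ — which is the standard way a
  ground-truth projection is produced for real data.

What the fixtures deliberately do **not** model: anisotropic or
depth-dependent PSFs, shot-noise-limited low photon counts, tissue
deformation over time, segmentation errors (masks are ground truth), or
multi-valued/folded surfaces. Passing tests therefore demonstrate
correctness of the geometry and of the extraction logic under controlled
layered-clutter conditions, not segmentation robustness on real images.

## Problem sizes and numerical choices

The test-suite fixtures are sized for completeness of the checks rather
than realism of scale: the notum-like recovery case is $256 \times 256
\times 32$ voxels, the planar series $160 \times 160 \times 48$ with ~240
cells, the curvature fixtures $240 \times 240$ with ~200 cells. Windowed
filters use integral images (cost independent of window size); the median
filter sorts per-pixel neighbourhoods block-wise. The standard-deviation
filter uses the population (1/N) normalisation — the choice cannot move
the argmax but is fixed for testability. All sliding filters use
symmetric (edge-inclusive) reflective padding. Fractional height-map
values are rounded half-up to address slices; sub-slice intensity
interpolation is deliberately not attempted. Degenerate inputs (collinear
contours, empty masks, windows larger than the image, surfaces leaving
the z range) raise errors or warnings rather than propagating nonsense.

## Open design points, resolved

* Gaussian pre-smoothing is applied *after* binning (to the binned
  plane); regularisation runs in binned space. Both choices keep cost
  symmetric with extraction and are flagged as conventions, not claims.
* Whether "orientation" is an XY-frame or apical-plane quantity is
  ambiguous; both are reported (`orientation_xy`,
  `ellipse_orientation`).
* The perturbation sign is $+1$ slice; the moved half is a contiguous arc
  (see above), seedable.
* The calibration `dz` scales every 3D metric, so file readers take it
  from the caller or a config; there is no silent default in the CLI.
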