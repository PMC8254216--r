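# epiproj

Local Z projection and distortion-corrected 3D morphometrics for curved
epithelia.

Quantitative imaging of epithelial tissue usually starts by projecting a
3D stack onto the 2D plane of the tissue, because cells are far easier to
segment in 2D. Two things routinely go wrong. First, the common maximum
intensity projection (MIP) mixes in signal from every layer of the volume
— auto-fluorescent cuticle above the cell layer, bright fat bodies below
it — and the projection becomes hard or impossible to segment. Second,
wherever the tissue is tilted or curved, the projection forshortens cell
geometry: a planar cell whose apical plane makes an angle θ with the
image plane loses a factor cos θ of its area in 2D, i.e. a relative area
error

> e_a = 1 − a_2D / a_3D = 1 − cos θ

which reaches 50% at θ = 60°, an angle that real tissues (brain
ventricles, tissue folds, embryo margins) do reach.

`epiproj` implements both halves of the remedy:

* **Local Z projection** — extract a *height-map* z = f(x, y) of the
  layer by finding, per pixel, the z slice where a windowed
  mean/standard-deviation filter responds most strongly (binning,
  Gaussian pre-smoothing and median regularisation included), then
  collect intensity only in a window `offset ± delta_z` around that
  surface, per channel. A two-pass streaming mode processes stacks larger
  than memory, reading each plane from disk at most twice.
* **Deprojection** — lift a 2D segmentation of the projection back onto
  the reference surface and measure each cell in 3D: area, perimeter,
  e_a and e_l, apical-plane slope and Euler angles, moment-equivalent
  ellipse (in-plane and XY), neighbour counts, and local mean/Gaussian
  curvature of the surface (Monge-patch formulas).
* **Synthetic epithelia** — a ground-truthed generator (curved surfaces,
  Voronoi cell lattices, cuticle/fat-body clutter, PSF, noise) so every
  claim is testable without external data, plus RMSE evaluation and
  parameter sweeps.

## Worked example

Generate a notum-like fixture (bump-shaped layer, cuticle above, fat
bodies below, SNR ≈ 3), recover the surface, project, and deproject its
segmentation:

```r
library(epiproj)

spec <- synthetic_preset("notum", seed = 1)   # 256 x 256 x 32, 200 cells
fx   <- synthetic_fixture(spec)

hm   <- extract_height_map(fx$stack)          # std filter, window 21
proj <- project_channel(fx$stack, 1, hm, channel_params(0, 1, "max"))

evaluate_projection(proj, fx$ideal_projection, hm = hm,
                    hm_truth = fx$hm_truth)
#> <eval_report> projection RMSE = 209.4, height-map RMSE = 0.6504 slices (65536 px)
rmse(mip(fx$stack), fx$ideal_projection)
#> [1] 338.915

dp <- deproject(fx$mask, hm, dx = spec$dx, dy = spec$dy, dz = spec$dz)
dp
#> <deproj> 200 cells (149 interior), smoothing sigma 3.83 um
#>   median e_a = 0.0811, median slope = 23.3 deg (interior cells)
head(dp$cells[, c("label", "area_2d", "area_3d", "err_area",
                  "slope_theta", "eccentricity", "n_neighbors")])
#>   label area_2d area_3d err_area slope_theta eccentricity n_neighbors
#> 1     1   12.62  14.159    0.109      27.230        0.659           6
#> 2     2   15.62  17.528    0.109      26.695        0.709           7
#> 3     3    9.58   9.612    0.003       4.227        0.606           5
#> 4     4   15.38  15.772    0.025      12.847        0.570           7
#> 5     5   14.06  14.258    0.014       8.573        0.650           7
#> 6     6   11.66  13.168    0.115      27.600        0.698           6
```

Reading the numbers: the height-map lands within two-thirds of a slice of
the true surface despite noise and clutter; the local projection is ~40%
closer to the ground-truth surface image than the MIP (whose error is
dominated by cuticle and fat-body bleed-through); and cells on the flank
of the bump (slope ≈ 27°) would carry an ~11% area error if measured in
2D — `area_3d` is the corrected value. `plot(dp, "err_area")` draws the
error map; `summary(dp)` aggregates interior (non-border) cells.

A command-line interface wraps the same functions
(`Rscript inst/cli/epi.R <heightmap|project|deproj|synth|eval> ...`);
see `epi_cli()`.

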