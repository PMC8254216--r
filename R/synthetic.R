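# Ground-truthed synthetic epithelia.
#
# Fixtures emulate the layered structure of confocal stacks of curved
# epithelia: a junctional membrane lattice wrapped on a single-valued
# surface z = f(x, y), optionally an auto-fluorescent "cuticle" sheet a few
# slices apical (lower z) of the layer, punctate bright "fat-body" spheres
# basal (higher z) of it, separable Gaussian PSF blur and pixel noise.
# Every fixture carries its ground truth (analytic surface, sampled
# height-map, label mask, ideal surface-intensity projection), so
# projection and morphometry can be scored without judgement calls.

#' Describe a synthetic epithelium fixture
#'
#' @param surface_kind one of `"flat"`, `"tilted_plane"`, `"gaussian_bump"`,
#'   `"sphere_cap"`, `"cylinder"`.
#' @param surface_args named list of surface parameters (micrometres unless
#'   noted): `z0` base height; `theta_deg` (tilted plane); `amplitude`,
#'   `width` (bump); `R`, `h` (sphere cap); `R` (cylinder).
#' @param ny,nx,nz grid size in pixels/slices.
#' @param dx,dy,dz voxel calibration in micrometres.
#' @param n_cells number of Voronoi cells.
#' @param membrane_width painted junction width in pixels.
#' @param membrane_thickness_slices odd number of z slices over which the
#'   junctional belt is painted (centred on the surface); real adherens
#'   junctions have an axial extent of one to two micrometres.
#' @param membrane_intensity,fill_intensity intensity of the junction
#'   lattice and of the diffuse signal between junctions at the surface
#'   (arbitrary units). With PSF blur the observed membrane amplitude is
#'   lower than the painted value; presets quote their signal-to-noise
#'   ratio as observed amplitude over noise sd.
#' @param cuticle_intensity,cuticle_offset_slices,cuticle_thickness_slices
#'   spurious auto-fluorescent sheet above the layer: peak intensity (0
#'   disables), distance above the surface and axial thickness in slices.
#' @param fatbody_intensity,n_fatbodies,fatbody_radius_px,fatbody_depth_slices
#'   bright spheres below the layer (`n_fatbodies = 0` disables); radius and
#'   depth are `c(min, max)` ranges.
#' @param psf_sigma `c(sigma_xy, sigma_z)` Gaussian PSF in pixels/slices
#'   (axial at least twice lateral, matching the elongated confocal PSF);
#'   `c(0, 0)` disables.
#' @param background constant baseline intensity (camera offset).
#' @param noise `list(kind = "none"|"gaussian"|"poisson", sd = )`; Gaussian
#'   sd is in intensity units.
#' @param seed integer; fully determines mask and stack.
#' @return an object of class `synthetic_spec`.
#' @seealso [synthetic_preset()] for ready-made study fixtures.
#' @export
synthetic_spec <- function(surface_kind = c("flat", "tilted_plane",
                                            "gaussian_bump", "sphere_cap",
                                            "cylinder"),
                           surface_args = list(),
                           ny = 128L, nx = 128L, nz = 16L,
                           dx = 0.25, dy = 0.25, dz = 1,
                           n_cells = 60L, membrane_width = 2L,
                           membrane_thickness_slices = 1L,
                           membrane_intensity = 600, fill_intensity = 0,
                           cuticle_intensity = 0, cuticle_offset_slices = 6L,
                           cuticle_thickness_slices = 3L,
                           fatbody_intensity = 0, n_fatbodies = 0L,
                           fatbody_radius_px = c(2L, 5L),
                           fatbody_depth_slices = c(5L, 10L),
                           psf_sigma = c(0, 0), background = 0,
                           noise = list(kind = "none"), seed = 1L) {
  surface_kind <- match.arg(surface_kind)
  check_calibration(dx, dy, dz)
  if (n_cells < 1L) stop("'n_cells' must be >= 1")
  if (is.null(noise$kind)) noise$kind <- "none"
  noise$kind <- match.arg(noise$kind, c("none", "gaussian", "poisson"))
  if (noise$kind == "gaussian" && (is.null(noise$sd) || noise$sd <= 0))
    stop("gaussian noise needs a positive 'sd'")
  if (length(psf_sigma) == 1L) psf_sigma <- c(psf_sigma, 2 * psf_sigma)
  structure(list(
    surface_kind = surface_kind, surface_args = surface_args,
    ny = as.integer(ny), nx = as.integer(nx), nz = as.integer(nz),
    dx = dx, dy = dy, dz = dz,
    n_cells = as.integer(n_cells),
    membrane_width = as.integer(membrane_width),
    membrane_thickness_slices = as.integer(membrane_thickness_slices),
    membrane_intensity = membrane_intensity,
    fill_intensity = fill_intensity,
    cuticle_intensity = cuticle_intensity,
    cuticle_offset_slices = as.integer(cuticle_offset_slices),
    cuticle_thickness_slices = as.integer(cuticle_thickness_slices),
    fatbody_intensity = fatbody_intensity,
    n_fatbodies = as.integer(n_fatbodies),
    fatbody_radius_px = fatbody_radius_px,
    fatbody_depth_slices = fatbody_depth_slices,
    psf_sigma = psf_sigma, background = background,
    noise = noise, seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' Ready-made study fixtures
#'
#' * `"flat"` — flat surface, clean membrane lattice; the zero-distortion
#'   control.
#' * `"plane"` — tilted plane (default 30 degrees) with a diffuse
#'   junctional sheet; the planar-distortion series.
#' * `"notum"` — 256 x 256 x 32 bump-shaped layer with an auto-fluorescent
#'   cuticle sheet above, bright fat-body spheres below, PSF blur and
#'   Gaussian noise at SNR ~ 3 (noise sd = membrane intensity / 3); the
#'   hard height-map-extraction case.
#' * `"sphere"` — spherical cap R = 50 um, h = 10 um; area-conservation and
#'   curvature checks.
#' * `"cylinder"` — cylinder R = 50 um along y; curvature check.
#' * `"bump"` — tall Gaussian bump with fine axial sampling
#'   (dz = 0.65 um); the slope/perturbation study.
#'
#' @param preset preset name.
#' @param ... overrides passed to [synthetic_spec()] fields.
#' @return a `synthetic_spec`.
#' @export
synthetic_preset <- function(preset = c("flat", "plane", "notum", "sphere",
                                        "cylinder", "bump"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    flat = list(surface_kind = "flat", surface_args = list(z0 = 5),
                ny = 128L, nx = 128L, nz = 12L, dx = 0.25, dy = 0.25, dz = 1,
                n_cells = 60L),
    plane = list(surface_kind = "tilted_plane",
                 surface_args = list(theta_deg = 30, z0 = 1.5),
                 ny = 160L, nx = 160L, nz = 48L, dx = 0.15, dy = 0.15, dz = 1,
                 n_cells = 240L, fill_intensity = 120),
    notum = list(surface_kind = "gaussian_bump",
                 surface_args = list(z0 = 10, amplitude = 12, width = 12),
                 ny = 256L, nx = 256L, nz = 32L, dx = 0.2, dy = 0.2, dz = 1,
                 n_cells = 200L, fill_intensity = 200,
                 membrane_thickness_slices = 3L, membrane_intensity = 1200,
                 cuticle_intensity = 500, cuticle_offset_slices = 6L,
                 fatbody_intensity = 1600, n_fatbodies = 8L,
                 psf_sigma = c(0.8, 1.6), background = 600,
                 noise = list(kind = "gaussian", sd = 200)),
    sphere = list(surface_kind = "sphere_cap",
                  surface_args = list(z0 = 1, R = 50, h = 10),
                  ny = 240L, nx = 240L, nz = 26L,
                  dx = 0.3, dy = 0.3, dz = 0.5,
                  n_cells = 220L, fill_intensity = 120),
    cylinder = list(surface_kind = "cylinder",
                    surface_args = list(z0 = 1, R = 50),
                    ny = 240L, nx = 240L, nz = 36L,
                    dx = 0.3, dy = 0.3, dz = 0.5,
                    n_cells = 200L, fill_intensity = 120),
    bump = list(surface_kind = "gaussian_bump",
                surface_args = list(z0 = 1, amplitude = 20, width = 12),
                ny = 256L, nx = 256L, nz = 36L,
                dx = 0.3, dy = 0.3, dz = 0.65,
                n_cells = 230L, fill_intensity = 120))
  args <- utils::modifyList(base, list(...))
  do.call(synthetic_spec, args)
}

#' Analytic surface and sampled ground-truth height-map
#'
#' @param spec a `synthetic_spec`.
#' @return list with `f` (closed-form surface, micrometres) and `hm_truth`
#'   (its sampling at pixel centres, 1-based fractional slice indices).
#'   Errors if the surface leaves the slice range `[2, nz - 1]` (so that
#'   one-slice accumulation windows always fit).
#' @export
make_surface <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  a <- spec$surface_args
  xc <- (spec$nx - 1) * spec$dx / 2
  yc <- (spec$ny - 1) * spec$dy / 2
  z0 <- if (is.null(a$z0)) 2 * spec$dz else a$z0
  f <- switch(spec$surface_kind,
    flat = function(x, y) rep_len(z0, length(x)),
    tilted_plane = {
      slope <- tan(a$theta_deg * pi / 180)
      function(x, y) z0 + slope * x
    },
    gaussian_bump = {
      A <- a$amplitude; w <- a$width
      function(x, y) z0 + A * exp(-((x - xc)^2 + (y - yc)^2) / (2 * w^2))
    },
    sphere_cap = {
      R <- a$R; h <- a$h
      function(x, y) {
        r2 <- (x - xc)^2 + (y - yc)^2
        z0 + pmax(0, sqrt(pmax(R^2 - r2, 0)) - (R - h))
      }
    },
    cylinder = {
      R <- a$R
      function(x, y) {
        sag0 <- sqrt(max(R^2 - xc^2, 0))
        z0 + sqrt(pmax(R^2 - (x - xc)^2, 0)) - sag0
      }
    })
  xs <- (seq_len(spec$nx) - 1) * spec$dx
  ys <- (seq_len(spec$ny) - 1) * spec$dy
  hm <- outer(ys, xs, function(y, x) f(x, y)) / spec$dz + 1
  if (min(hm) < 2 || max(hm) > spec$nz - 1)
    stop(sprintf(
      "surface exits the usable z range: slices [%.2f, %.2f] vs [2, %d]",
      min(hm), max(hm), spec$nz - 1L))
  list(f = f, hm_truth = hm)
}

# Poisson-disc seed points by dart throwing; the exclusion radius shrinks
# until the requested count fits, so the draw always succeeds and stays
# fully determined by the RNG state.
poisson_disc_seeds <- function(nx, ny, n) {
  r <- 0.75 * sqrt(nx * ny / n)
  pts <- matrix(numeric(0), 0L, 2L)
  misses <- 0L
  while (nrow(pts) < n) {
    cand <- c(stats::runif(1, 0.5, nx - 0.5), stats::runif(1, 0.5, ny - 0.5))
    ok <- nrow(pts) == 0L ||
      min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= r^2
    if (ok) {
      pts <- rbind(pts, cand)
      misses <- 0L
    } else {
      misses <- misses + 1L
      if (misses > 200L) { r <- r * 0.85; misses <- 0L }
    }
  }
  colnames(pts) <- c("x", "y")
  pts
}

#' Voronoi epithelium label mask
#'
#' Poisson-disc-sampled seeds tessellate the grid into `n_cells` convex
#' regions (labels 1..n), separated by a 1-pixel junction band of
#' background; the outermost pixel frame is background too. Fully
#' determined by `spec$seed`.
#'
#' @param spec a `synthetic_spec`.
#' @return list with `mask` (integer label matrix) and `seeds` (n x 2
#'   pixel coordinates).
#' @export
make_epithelium_mask <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1L)
  seeds <- poisson_disc_seeds(spec$nx, spec$ny, spec$n_cells)
  px <- seq_len(spec$nx) - 1
  py <- seq_len(spec$ny) - 1
  best <- matrix(Inf, spec$ny, spec$nx)
  lab <- matrix(0L, spec$ny, spec$nx)
  for (s in seq_len(nrow(seeds))) {
    d2 <- outer((py - seeds[s, 2])^2, (px - seeds[s, 1])^2, `+`)
    upd <- d2 < best
    lab[upd] <- s
    best[upd] <- d2[upd]
  }
  junction <- matrix(FALSE, spec$ny, spec$nx)
  junction[, -spec$nx] <- junction[, -spec$nx] | (lab[, -spec$nx] != lab[, -1])
  junction[-spec$ny, ] <- junction[-spec$ny, ] | (lab[-spec$ny, ] != lab[-1, ])
  junction[c(1L, spec$ny), ] <- TRUE
  junction[, c(1L, spec$nx)] <- TRUE
  lab[junction] <- 0L
  list(mask = lab, seeds = seeds)
}

#' Render the 3D stack of a synthetic epithelium
#'
#' Paints the membrane lattice (and optional diffuse fill) on the surface,
#' adds the cuticle sheet and fat-body spheres if requested, applies the
#' separable Gaussian PSF, adds the baseline and finally the noise. Also
#' returns the ideal projection: the noiseless (but blurred) volume sampled
#' at the true surface, i.e. what a perfect height-map would collect with
#' offset 0 and delta_z 0.
#'
#' @param spec a `synthetic_spec`.
#' @param surface output of [make_surface()].
#' @param mask output of [make_epithelium_mask()] (or a label matrix).
#' @return list with `stack` (a `volume_stack`), `ideal_projection` and
#'   `hm_truth`.
#' @export
render_stack <- function(spec, surface = make_surface(spec),
                         mask = make_epithelium_mask(spec)) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.list(mask)) mask <- mask$mask
  set.seed(spec$seed + 2L)
  ny <- spec$ny; nx <- spec$nx; nz <- spec$nz
  arr <- array(0, c(ny, nx, nz))
  zidx <- round_half_up(surface$hm_truth)
  memb <- dilate_chebyshev(mask == 0L, max(0L, (spec$membrane_width - 1L) %/% 2L))
  lin <- function(rows, cols, zs) rows + ny * (cols - 1L) + ny * nx * (zs - 1L)
  allr <- row(mask); allc <- col(mask)
  # membrane lattice on the surface (painted over the belt's axial extent)
  th <- max(1L, spec$membrane_thickness_slices)
  zoffs <- seq.int(-(th %/% 2L), th %/% 2L)
  selm <- which(memb)
  self <- which(!memb)
  for (dzo in zoffs) {
    zs <- pmin(spec$nz, pmax(1L, zidx + dzo))
    arr[lin(allr[selm], allc[selm], zs[selm])] <- spec$membrane_intensity
    if (spec$fill_intensity > 0)
      arr[lin(allr[self], allc[self], zs[self])] <- spec$fill_intensity
  }
  # auto-fluorescent cuticle sheet, a few slices apical (lower z)
  if (spec$cuticle_intensity > 0) {
    tex <- gaussian_smooth(matrix(stats::runif(ny * nx), ny, nx), 1.5)
    tex <- (tex - min(tex)) / max(1e-12, diff(range(tex)))
    val <- spec$cuticle_intensity * (0.3 + 0.7 * tex)
    tc <- max(1L, spec$cuticle_thickness_slices)
    for (dzo in seq.int(-(tc %/% 2L), tc %/% 2L)) {
      zcut <- pmax(1L, zidx - spec$cuticle_offset_slices + dzo)
      arr[lin(allr, allc, zcut)] <- pmax(arr[lin(allr, allc, zcut)], val)
    }
  }
  # punctate fat bodies, basal (higher z) of the layer
  if (spec$n_fatbodies > 0L && spec$fatbody_intensity > 0) {
    for (k in seq_len(spec$n_fatbodies)) {
      cx <- stats::runif(1, 1, nx); cy <- stats::runif(1, 1, ny)
      rad <- stats::runif(1, spec$fatbody_radius_px[1], spec$fatbody_radius_px[2])
      depth <- stats::runif(1, spec$fatbody_depth_slices[1],
                            spec$fatbody_depth_slices[2])
      cz <- min(nz, round(surface$hm_truth[round_half_up(cy), round_half_up(cx)] + depth))
      rz <- max(1, rad * spec$dx / spec$dz)
      zr <- max(1L, floor(cz - rz)):min(nz, ceiling(cz + rz))
      yr <- max(1L, floor(cy - rad)):min(ny, ceiling(cy + rad))
      xr <- max(1L, floor(cx - rad)):min(nx, ceiling(cx + rad))
      for (z in zr) {
        d2 <- outer(((yr - cy) / rad)^2, ((xr - cx) / rad)^2, `+`) +
          ((z - cz) / rz)^2
        sl <- arr[yr, xr, z]
        sl[d2 <= 1] <- spec$fatbody_intensity
        arr[yr, xr, z] <- sl
      }
    }
  }
  # separable Gaussian PSF
  if (spec$psf_sigma[1] > 0)
    for (z in seq_len(nz))
      arr[, , z] <- gaussian_smooth(arr[, , z], spec$psf_sigma[1])
  if (spec$psf_sigma[2] > 0) {
    k <- gaussian_kernel(spec$psf_sigma[2])
    r <- (length(k) - 1L) %/% 2L
    zi <- function(z) pmin(nz, pmax(1L, z))
    out <- array(0, dim(arr))
    for (t in seq_along(k))
      out <- out + k[t] * arr[, , zi(seq_len(nz) + t - 1L - r), drop = FALSE]
    arr <- out
  }
  arr <- arr + spec$background
  # ground-truth projection: the noiseless volume sampled at the true
  # surface (what a perfect height-map would collect, offset 0, delta_z 0)
  ideal <- matrix(arr[lin(allr, allc, zidx)], ny, nx)
  if (spec$noise$kind == "gaussian") {
    arr <- arr + stats::rnorm(length(arr), sd = spec$noise$sd)
    arr[arr < 0] <- 0
  } else if (spec$noise$kind == "poisson") {
    arr <- array(stats::rpois(length(arr), lambda = arr), dim(arr))
  }
  list(stack = volume_stack(arr, dx = spec$dx, dy = spec$dy, dz = spec$dz),
       ideal_projection = ideal, hm_truth = surface$hm_truth)
}

# Binary dilation with a (2r+1)^2 square structuring element.
dilate_chebyshev <- function(binary, r) {
  if (r < 1L) return(binary)
  ny <- nrow(binary); nx <- ncol(binary)
  out <- binary
  for (di in (-r):r) for (dj in (-r):r) {
    if (di == 0L && dj == 0L) next
    ri <- pmin(pmax(seq_len(ny) + di, 1L), ny)
    cj <- pmin(pmax(seq_len(nx) + dj, 1L), nx)
    out <- out | binary[ri, cj]
  }
  out
}

#' Generate a complete synthetic fixture
#'
#' Runs [make_surface()], [make_epithelium_mask()] and [render_stack()] and
#' bundles everything with its ground truth.
#'
#' @param spec a `synthetic_spec` (e.g. from [synthetic_preset()]).
#' @return list with `spec`, `f`, `hm_truth`, `mask`, `seeds`, `stack` and
#'   `ideal_projection`.
#' @export
synthetic_fixture <- function(spec) {
  surf <- make_surface(spec)
  em <- make_epithelium_mask(spec)
  rs <- render_stack(spec, surf, em$mask)
  list(spec = spec, f = surf$f, hm_truth = surf$hm_truth,
       mask = em$mask, seeds = em$seeds,
       stack = rs$stack, ideal_projection = rs$ideal_projection)
}
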