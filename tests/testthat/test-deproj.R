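# Deprojection morphometrics.

test_that("on a flat surface every 3D metric equals its 2D counterpart", {
  spec <- synthetic_preset("flat", seed = 7)
  fx <- synthetic_fixture(spec)
  dp <- deproject(fx$mask, fx$hm_truth, dx = spec$dx, dy = spec$dy,
                  dz = spec$dz)
  cells <- dp$cells
  expect_true(all(cells$err_area == 0))
  expect_true(all(cells$err_perim == 0))
  expect_true(all(cells$slope_theta == 0))
  expect_equal(cells$area_3d, cells$area_2d)
  expect_equal(cells$perim_3d, cells$perim_2d)
  expect_equal(cells$eccentricity, cells$eccentricity_xy, tolerance = 1e-9)
})

test_that("planar cells at slope theta obey e_a = 1 - cos(theta) exactly", {
  spec <- synthetic_preset("flat", seed = 7)
  mask <- make_epithelium_mask(spec)$mask
  for (th in c(20, 45, 60)) {
    surf <- analytic_surface(function(x, y) x * tan(th * pi / 180))
    dp <- deproject(mask, dx = spec$dx, dy = spec$dy, dz = spec$dz,
                    surface = surf)
    expect_equal(dp$cells$err_area, rep(1 - cos(th * pi / 180),
                                        nrow(dp$cells)),
                 tolerance = 1e-9)
    expect_equal(dp$cells$slope_theta, rep(th, nrow(dp$cells)),
                 tolerance = 1e-6)
  }
})

test_that("polygon areas agree with pixel counting and a3D >= a2D on a bump", {
  spec <- synthetic_preset("bump", seed = 15, ny = 128L, nx = 128L,
                           n_cells = 60L,
                           surface_args = list(z0 = 1, amplitude = 12,
                                               width = 8))
  fx <- synthetic_fixture(spec)
  dp <- deproject(fx$mask, fx$hm_truth, dx = spec$dx, dy = spec$dy,
                  dz = spec$dz)
  cells <- dp$cells
  px_area <- spec$dx * spec$dy
  for (i in seq_len(nrow(cells))) {
    npx <- sum(fx$mask == cells$label[i])
    # boundary convention: contour area within ~ one half-perimeter-pixel
    tol <- cells$perim_2d[i] * spec$dx
    expect_lt(abs(cells$area_2d[i] - npx * px_area), tol)
  }
  expect_true(all(cells$area_3d >= cells$area_2d * (1 - 1e-9)))
  expect_true(all(cells$err_area >= -1e-9 & cells$err_area < 1))
})

test_that("e_a is bounded below by the planar law of the fitted slope", {
  spec <- synthetic_preset("bump", seed = 16, ny = 128L, nx = 128L,
                           n_cells = 60L,
                           surface_args = list(z0 = 1, amplitude = 12,
                                               width = 8))
  fx <- synthetic_fixture(spec)
  dp <- deproject(fx$mask, fx$hm_truth, dx = spec$dx, dy = spec$dy,
                  dz = spec$dz)
  cells <- dp$cells[!dp$cells$on_border, ]
  lower <- 1 - cos(cells$slope_theta * pi / 180)
  # non-planar contours can only increase the error beyond the planar law,
  # up to a small fitting slack
  expect_true(all(cells$err_area >= lower - 0.02))
})

test_that("deprojected metrics are invariant to rotation about the z axis", {
  set.seed(17)
  bump <- analytic_surface(function(x, y)
    6 * exp(-((x - 10)^2 + (y - 10)^2) / 18) + 1)
  rotate <- function(p, a, ctr = c(10, 10)) {
    R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
    sweep(sweep(p, 2, ctr) %*% t(R), 2, -ctr)
  }
  bump_rot <- analytic_surface(function(x, y) {
    q <- rotate(cbind(x, y), -pi / 5)
    6 * exp(-((q[, 1] - 10)^2 + (q[, 2] - 10)^2) / 18) + 1
  })
  for (k in 1:5) {
    poly <- sweep(random_polygon(14, 1, 2.4), 2, c(10 + runif(1, -2, 2),
                                                   10 + runif(1, -2, 2)), "+")
    c3a <- lift_polygon(poly, bump)
    c3b <- lift_polygon(rotate(poly, pi / 5), bump_rot)
    expect_equal(polygon_area_3d(c3b), polygon_area_3d(c3a),
                 tolerance = 1e-6)
    expect_equal(polygon_perimeter_3d(c3b), polygon_perimeter_3d(c3a),
                 tolerance = 1e-6)
    expect_equal(fit_ellipse_3d(c3b)$eccentricity,
                 fit_ellipse_3d(c3a)$eccentricity, tolerance = 1e-6)
    pa <- mean(c3a[, 1:2]) # centroids rotate with the polygon
    cva <- surface_curvature(bump, mean(c3a[, 1]), mean(c3a[, 2]))
    cvb <- surface_curvature(bump_rot, mean(c3b[, 1]), mean(c3b[, 2]))
    expect_equal(cvb$mean_curvature, cva$mean_curvature, tolerance = 1e-2)
    expect_equal(cvb$gaussian_curvature, cva$gaussian_curvature,
                 tolerance = 1e-2)
  }
})

test_that("border cells are flagged and excluded from summaries", {
  spec <- synthetic_preset("flat", seed = 7)
  fx <- synthetic_fixture(spec)
  dp <- deproject(fx$mask, fx$hm_truth, dx = spec$dx, dy = spec$dy,
                  dz = spec$dz)
  expect_true(any(dp$cells$on_border))
  s <- summary(dp)
  expect_equal(attr(s, "n_cells"), sum(!dp$cells$on_border))
})

test_that("zero-amplitude perturbation changes nothing", {
  spec <- synthetic_preset("flat", seed = 7, ny = 64L, nx = 64L,
                           n_cells = 20L)
  fx <- synthetic_fixture(spec)
  dp <- deproject(fx$mask, fx$hm_truth, dx = spec$dx, dy = spec$dy,
                  dz = spec$dz)
  pert <- perturb_contours(dp, dz_slice = 0, seed = 1)
  expect_true(all(pert$cells$rel_area_diff == 0))
  expect_true(all(pert$cells$rel_perim_diff == 0))
})

test_that("perturbing two vertices of a flat square matches hand geometry", {
  sq <- list(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10), 0))
  dz <- 0.65
  pert <- perturb_contours(sq, dz_slice = dz, seed = 5, vertices = "block")
  # two adjacent vertices raised by dz: recompute the lifted quadrilateral
  idx <- pert$cells
  lifted <- sq[[1]]
  # reproduce the same RNG draw to know which arc moved
  set.seed(5); start <- sample.int(4, 1)
  moved <- ((start - 1 + 0:1) %% 4) + 1
  lifted[moved, 3] <- dz
  expect_equal(idx$area_3d_perturbed, polygon_area_3d(lifted))
  expect_equal(idx$perim_3d_perturbed, perimeter_oracle(lifted))
  expect_gt(idx$rel_perim_diff, 0)
})

test_that("perturbation is seed-reproducible and modes differ as expected", {
  spec <- synthetic_preset("bump", seed = 18, ny = 128L, nx = 128L,
                           n_cells = 60L,
                           surface_args = list(z0 = 1, amplitude = 12,
                                               width = 8))
  fx <- synthetic_fixture(spec)
  dp <- deproject(fx$mask, fx$hm_truth, dx = spec$dx, dy = spec$dy,
                  dz = spec$dz)
  p1 <- perturb_contours(dp, spec$dz, seed = 42)
  p2 <- perturb_contours(dp, spec$dz, seed = 42)
  expect_identical(p1$cells, p2$cells)
  pr <- perturb_contours(dp, spec$dz, seed = 42, vertices = "random")
  # scattered perturbation of dense contours is far harsher on the perimeter
  expect_gt(pr$summary$mean_rel_perim_diff,
            5 * p1$summary$mean_rel_perim_diff)
})

test_that("shape mismatches are rejected", {
  expect_error(deproject(matrix(1L, 4, 4), matrix(1, 3, 3)), "extent")
})
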