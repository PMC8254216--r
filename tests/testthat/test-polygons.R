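# Mask tracing and polygon geometry.

test_that("a square region traces to a polygon of the right area and flags", {
  mask <- matrix(0L, 14, 14)
  mask[3:12, 3:12] <- 1L
  polys <- mask_to_polygons(mask)
  expect_length(polys, 1L)
  p <- polys[[1]]
  a <- abs(shoelace_oracle(p$vertices[, 1], p$vertices[, 2]))
  expect_equal(a, 100, tolerance = 0.01)  # half-pixel boundary convention
  expect_false(p$on_border)
  expect_equal(p$n_neighbors, 0L)
  # CCW orientation
  expect_gt(shoelace_oracle(p$vertices[, 1], p$vertices[, 2]), 0)
})

test_that("adjacent regions list each other as neighbours", {
  mask <- matrix(0L, 10, 12)
  mask[2:9, 2:5] <- 1L
  mask[2:9, 7:11] <- 2L   # separated by a 1-px junction band
  polys <- mask_to_polygons(mask)
  expect_equal(polys[[1]]$neighbor_labels, 2L)
  expect_equal(polys[[2]]$neighbor_labels, 1L)
  expect_true(polys[[2]]$on_border)  # touches column 11? no: 12 is border
})

test_that("neighbour counts match the brute-force adjacency oracle", {
  spec <- synthetic_preset("flat", seed = 12, ny = 80L, nx = 80L,
                           n_cells = 25L)
  mask <- make_epithelium_mask(spec)$mask
  polys <- mask_to_polygons(mask)
  oracle <- adjacency_oracle(mask, 2L)
  for (p in polys)
    expect_equal(p$neighbor_labels, oracle[[as.character(p$label)]],
                 info = paste("label", p$label))
})

test_that("binary junction masks are converted by component labelling", {
  mask <- matrix(1L, 11, 11)
  mask[6, ] <- 0L  # junction line splits in two
  polys <- mask_to_polygons(mask)
  expect_length(polys, 2L)
  expect_setequal(vapply(polys, `[[`, 1L, "label"), c(1L, 2L))
})

test_that("empty masks warn and return nothing", {
  expect_warning(p <- mask_to_polygons(matrix(0L, 5, 5)), "empty")
  expect_length(p, 0L)
})

test_that("lifting evaluates the surface at each vertex and preserves order", {
  sq <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  flat <- analytic_surface(function(x, y) rep(0, length(x)))
  expect_equal(lift_polygon(sq, flat), cbind(sq, z = 0))
  tilt <- analytic_surface(function(x, y) x * tan(pi / 6))
  l <- lift_polygon(sq, tilt)
  expect_equal(l[, 3], c(0, tan(pi / 6), tan(pi / 6), 0))
  set.seed(3)
  bump <- analytic_surface(function(x, y) 2 * exp(-(x^2 + y^2) / 8))
  poly <- random_polygon(12)
  l2 <- lift_polygon(poly, bump)
  expect_equal(l2[, 3], bump$f(poly[, 1], poly[, 2]))
})

test_that("3D area is exact for planar polygons and a tilted unit square", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  expect_equal(polygon_area_3d(sq), 1)
  # unit square rotated to 60 degrees about one side: area 1, projection 0.5
  th <- pi / 3
  sq60 <- cbind(c(0, 1, 1, 0), c(0, 0, cos(th), cos(th)),
                c(0, 0, sin(th), sin(th)))
  expect_equal(polygon_area_3d(sq60), 1, tolerance = 1e-12)
  expect_equal(abs(shoelace_oracle(sq60[, 1], sq60[, 2])), 0.5)
  set.seed(8)
  for (k in 1:20) {
    poly <- random_polygon(sample(5:12, 1))
    a2 <- abs(shoelace_oracle(poly[, 1], poly[, 2]))
    # embed in a random tilted plane
    th <- runif(1, 0, 1.2); ph <- runif(1, 0, 2 * pi)
    u <- c(cos(ph), sin(ph), 0)
    v <- c(-sin(ph) * cos(th), cos(ph) * cos(th), sin(th))
    c3 <- outer(poly[, 1], u) + outer(poly[, 2], v)
    expect_equal(polygon_area_3d(c3), a2, tolerance = 1e-9 * a2)
  }
})

test_that("3D perimeter sums Euclidean edge lengths", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  expect_equal(polygon_perimeter_3d(sq), 4)
  lifted <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), c(0, 1, 1, 0))
  expect_equal(polygon_perimeter_3d(lifted), 2 + 2 * sqrt(2))
  set.seed(9)
  for (k in 1:20) {
    c3 <- cbind(random_polygon(7), runif(7))
    expect_equal(polygon_perimeter_3d(c3), perimeter_oracle(c3),
                 tolerance = 1e-12)
  }
})

test_that("plane fits recover analytic slopes and match the TLS oracle", {
  flat <- cbind(random_polygon(8), 0)
  pf <- fit_cell_plane(flat)
  expect_equal(pf$slope_theta, 0)
  expect_equal(pf$normal, c(0, 0, 1))
  # z = x tan(40 deg)
  poly <- random_polygon(10)
  c3 <- cbind(poly, poly[, 1] * tan(40 * pi / 180))
  pf2 <- fit_cell_plane(c3)
  expect_equal(pf2$slope_theta, 40, tolerance = 1e-6)
  set.seed(10)
  for (k in 1:10) {
    poly <- random_polygon(24)
    z <- 0.8 * poly[, 1] - 0.3 * poly[, 2] + rnorm(24, sd = 0.02)
    c3 <- cbind(poly, z)
    pf3 <- fit_cell_plane(c3)
    expect_equal(pf3$normal, tls_plane_oracle(c3), tolerance = 1e-9)
  }
  expect_error(fit_cell_plane(cbind(0:3, 0:3, 0)), "collinear")
})

test_that("Euler angles are a valid Z-X'-Z'' factorisation of the plane frame", {
  rotz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  rotx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
  set.seed(12)
  for (k in 1:10) {
    poly <- random_polygon(16)
    c3 <- cbind(poly, runif(1, -1, 1) * poly[, 1] + runif(1, -1, 1) * poly[, 2])
    pf <- fit_cell_plane(c3)
    e <- pf$euler * pi / 180
    R <- rotz(e[1]) %*% rotx(e[2]) %*% rotz(e[3])
    expect_equal(R, cbind(pf$u, pf$v, pf$normal), tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(pf$euler[["beta"]], pf$slope_theta, tolerance = 1e-9)
  }
})

test_that("moment-equivalent ellipses: circle, rectangle, tilted circle", {
  ang <- seq(0, 2 * pi, length.out = 65)[-65]
  r <- 3
  circle <- cbind(r * cos(ang), r * sin(ang), 0)
  el <- fit_ellipse_3d(circle)
  expect_equal(unname(el$semi_axes), c(r, r), tolerance = 1e-3)
  expect_lt(el$eccentricity, 0.02)
  # 2:1 rectangle: eccentricity sqrt(1 - 1/4), long axis along x
  rect <- cbind(c(-1, 1, 1, -1), c(-0.5, -0.5, 0.5, 0.5), 0)
  el2 <- fit_ellipse_3d(rect)
  expect_equal(el2$eccentricity, sqrt(3) / 2, tolerance = 1e-12)
  expect_equal(abs(el2$orientation), 0, tolerance = 1e-9)
  # circle on a 60-degree slope: in-plane measurement removes the tilt
  th <- pi / 3
  tilted <- cbind(r * cos(ang), r * sin(ang) * cos(th), r * sin(ang) * sin(th))
  el3 <- fit_ellipse_3d(tilted)
  expect_lt(el3$eccentricity, 0.02)
  elxy <- epiproj:::fit_ellipse_2d(tilted[, 1:2])
  expect_equal(elxy$eccentricity, sqrt(3) / 2, tolerance = 1e-3)
})
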