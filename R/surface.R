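# Continuous reference surface z = f(x, y) in micrometres.
#
# Grid surfaces are built from a height-map: Gaussian smoothing (sigma of
# the order of one cell diameter, to suppress the staircase left by integer
# slice positions) followed by conversion to micrometres and bilinear
# evaluation. Analytic surfaces wrap a closed-form f and are mostly used by
# the synthetic fixtures and in tests.

#' Build a reference surface from a height-map
#'
#' @param hm height-map matrix (1-based slice indices, from
#'   [extract_height_map()] or ground truth).
#' @param dx,dy pixel size in micrometres.
#' @param dz slice spacing in micrometres.
#' @param sigma_um Gaussian smoothing sigma in micrometres; the recommended
#'   value is the median cell diameter. 0 disables smoothing.
#' @return an object of class `reference_surface`.
#' @details Smoothing uses a normalised kernel, so constant maps are
#'   preserved exactly and the smoothed value range never exceeds the input
#'   range. The surface is defined over the full pixel grid; evaluation
#'   outside is clamped to the border.
#' @export
reference_surface <- function(hm, dx = 1, dy = 1, dz = 1, sigma_um = 0) {
  stopifnot(is.matrix(hm))
  check_calibration(dx, dy, dz)
  if (!is.finite(sigma_um) || sigma_um < 0) stop("'sigma_um' must be >= 0")
  z <- if (sigma_um > 0)
    gaussian_smooth(hm, c(sigma_um / dy, sigma_um / dx)) else hm
  structure(list(kind = "grid", zgrid = (z - 1) * dz,
                 dx = dx, dy = dy, dz = dz, sigma_um = sigma_um,
                 xmax = (ncol(hm) - 1) * dx, ymax = (nrow(hm) - 1) * dy),
            class = "reference_surface")
}

#' Wrap a closed-form surface function
#'
#' @param f vectorised function `(x, y)` in micrometres returning z in
#'   micrometres.
#' @param step finite-difference step in micrometres used by
#'   [surface_curvature()].
#' @param dz slice spacing (kept for provenance; analytic surfaces are
#'   already in micrometres).
#' @return an object of class `reference_surface`.
#' @export
analytic_surface <- function(f, step = 0.25, dz = 1) {
  stopifnot(is.function(f))
  structure(list(kind = "analytic", f = f, step = step, dz = dz,
                 sigma_um = 0),
            class = "reference_surface")
}

#' Evaluate the surface height at (x, y)
#'
#' @param surface a `reference_surface`.
#' @param x,y coordinates in micrometres (vectorised).
#' @return z in micrometres.
#' @export
surface_height <- function(surface, x, y) {
  stopifnot(inherits(surface, "reference_surface"))
  if (surface$kind == "analytic") return(surface$f(x, y))
  bilinear_sample(surface$zgrid, y / surface$dy, x / surface$dx)
}

#' @export
print.reference_surface <- function(x, ...) {
  if (x$kind == "grid") {
    cat(sprintf("<reference_surface> grid %d x %d px (%.3g x %.3g um), smoothing sigma %.3g um\n",
                nrow(x$zgrid), ncol(x$zgrid), x$ymax, x$xmax, x$sigma_um))
    cat(sprintf("  z range: [%.3g, %.3g] um\n", min(x$zgrid), max(x$zgrid)))
  } else {
    cat("<reference_surface> analytic\n")
  }
  invisible(x)
}

#' Local mean and Gaussian curvature of the surface
#'
#' Curvatures of the Monge patch z = f(x, y) from finite differences:
#' \deqn{H = -\frac{(1+f_y^2) f_{xx} - 2 f_x f_y f_{xy} + (1+f_x^2) f_{yy}}
#'            {2 (1+f_x^2+f_y^2)^{3/2}}, \quad
#'       K = \frac{f_{xx} f_{yy} - f_{xy}^2}{(1+f_x^2+f_y^2)^2}.}
#' The sign convention makes `H > 0` for dome-like surfaces (local maximum
#' in z, tissue bulging away from the objective). A sphere of radius R gives
#' `H = 1/R` and `K = 1/R^2`; a cylinder gives `H = 1/(2R)`, `K = 0`.
#'
#' For grid surfaces the derivative fields are computed once by central
#' differences on the smoothed grid (one-sided at the border) and
#' interpolated bilinearly at the query points; for analytic surfaces
#' central differences of `f` with step `surface$step` are used directly.
#'
#' @param surface a `reference_surface`.
#' @param x,y query coordinates in micrometres (vectorised).
#' @return data.frame with columns `mean_curvature` (1/um) and
#'   `gaussian_curvature` (1/um^2).
#' @export
surface_curvature <- function(surface, x, y) {
  stopifnot(inherits(surface, "reference_surface"))
  if (surface$kind == "analytic") {
    h <- surface$step
    f <- surface$f
    fx  <- (f(x + h, y) - f(x - h, y)) / (2 * h)
    fy  <- (f(x, y + h) - f(x, y - h)) / (2 * h)
    fxx <- (f(x + h, y) - 2 * f(x, y) + f(x - h, y)) / h^2
    fyy <- (f(x, y + h) - 2 * f(x, y) + f(x, y - h)) / h^2
    fxy <- (f(x + h, y + h) - f(x + h, y - h) -
            f(x - h, y + h) + f(x - h, y - h)) / (4 * h^2)
  } else {
    d <- surface_derivative_grids(surface)
    r0 <- y / surface$dy; c0 <- x / surface$dx
    fx  <- bilinear_sample(d$fx, r0, c0)
    fy  <- bilinear_sample(d$fy, r0, c0)
    fxx <- bilinear_sample(d$fxx, r0, c0)
    fyy <- bilinear_sample(d$fyy, r0, c0)
    fxy <- bilinear_sample(d$fxy, r0, c0)
  }
  g <- 1 + fx^2 + fy^2
  H <- -((1 + fy^2) * fxx - 2 * fx * fy * fxy + (1 + fx^2) * fyy) /
    (2 * g^1.5)
  K <- (fxx * fyy - fxy^2) / g^2
  data.frame(mean_curvature = H, gaussian_curvature = K)
}

# Central differences on the z grid (um), one-sided at the borders.
surface_derivative_grids <- function(surface) {
  z <- surface$zgrid
  dx <- surface$dx; dy <- surface$dy
  ny <- nrow(z); nx <- ncol(z)
  dcol <- function(m) {  # d/dx: along columns
    out <- m
    out[, 2:(nx - 1)] <- (m[, 3:nx] - m[, 1:(nx - 2)]) / (2 * dx)
    out[, 1] <- (m[, 2] - m[, 1]) / dx
    out[, nx] <- (m[, nx] - m[, nx - 1]) / dx
    out
  }
  drow <- function(m) {  # d/dy: along rows
    out <- m
    out[2:(ny - 1), ] <- (m[3:ny, ] - m[1:(ny - 2), ]) / (2 * dy)
    out[1, ] <- (m[2, ] - m[1, ]) / dy
    out[ny, ] <- (m[ny, ] - m[ny - 1, ]) / dy
    out
  }
  fx <- dcol(z); fy <- drow(z)
  list(fx = fx, fy = fy, fxx = dcol(fx), fyy = drow(fy), fxy = drow(fx))
}
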