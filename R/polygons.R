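# Cell polygons: tracing label masks, lifting onto the surface, and the
# geometric measurements (area, perimeter, plane fit, moment-equivalent
# ellipse).
#
# Coordinate conventions: pixel centres sit at integer 0-based indices;
# physical coordinates are index * pixel size, x along columns, y along
# rows, both in micrometres. Polygons are stored as n x 2 (or n x 3)
# matrices of open rings (last vertex != first), counter-clockwise in the
# (x, y) plane.

#' Trace cell polygons from a label mask
#'
#' Each labelled region is traced along its boundary (sub-pixel contour at
#' the 0.5 iso-level, i.e. midway between region and background pixel
#' centres). Binary masks (values 0/1) are first converted by 4-connected
#' component labelling of the non-zero regions, the zero band being the
#' junction skeleton. Neighbour labels are the regions that touch within a
#' 2-pixel dilation; cells touching the image border are flagged.
#'
#' @param mask integer label matrix (0 = background/junctions).
#' @param dx,dy pixel size in micrometres.
#' @return an object of class `cell_polygons`: a list of cells, each with
#'   `label`, `vertices` (n x 2 matrix, um, CCW), `neighbor_labels`,
#'   `n_neighbors`, `on_border`, `area_px` and `centroid_px`.
#' @export
mask_to_polygons <- function(mask, dx = 1, dy = 1) {
  stopifnot(is.matrix(mask))
  check_calibration(dx, dy, 1)
  mask <- round(mask)
  if (all(mask %in% c(0, 1))) mask <- label_components(mask)
  labels <- sort(unique(mask[mask > 0]))
  if (length(labels) == 0L) {
    warning("empty mask: no labelled regions")
    return(structure(list(), class = "cell_polygons",
                     dx = dx, dy = dy, mask_dim = dim(mask)))
  }
  adj <- label_adjacency(mask, reach = 2L)
  ny <- nrow(mask); nx <- ncol(mask)
  cells <- vector("list", length(labels))
  for (i in seq_along(labels)) {
    lab <- labels[i]
    idx <- which(mask == lab, arr.ind = TRUE)
    # within one pixel of the edge: covers masks whose junction band or
    # background frame separates every region from the border proper
    on_border <- any(idx[, 1] <= 2L | idx[, 1] >= ny - 1L |
                     idx[, 2] <= 2L | idx[, 2] >= nx - 1L)
    r0 <- max(1L, min(idx[, 1]) - 2L); r1 <- min(ny, max(idx[, 1]) + 2L)
    c0 <- max(1L, min(idx[, 2]) - 2L); c1 <- min(nx, max(idx[, 2]) + 2L)
    sub <- (mask[r0:r1, c0:c1, drop = FALSE] == lab) * 1
    # guard ring of zeros so the contour always closes
    sub <- rbind(0, cbind(0, sub, 0), 0)
    rows <- (r0 - 2L):(r1)        # 0-based pixel rows of `sub`
    cols <- (c0 - 2L):(c1)
    cl <- grDevices::contourLines(x = rows, y = cols, z = sub, levels = 0.5)
    if (length(cl) == 0L) next
    areas <- vapply(cl, function(p) abs(poly_signed_area(cbind(p$y, p$x))),
                    numeric(1))
    if (length(cl) > 1L)
      warning(sprintf("label %d has %d boundary contours; keeping the largest",
                      lab, length(cl)))
    p <- cl[[which.max(areas)]]
    v <- cbind(x = p$y * dx, y = p$x * dy)   # contour x-arg = rows = y axis
    n <- nrow(v)
    if (all(v[1, ] == v[n, ])) v <- v[-n, , drop = FALSE]
    if (nrow(v) < 3L) next
    if (poly_signed_area(v) < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]
    nb <- adj[[as.character(lab)]]
    if (is.null(nb)) nb <- integer(0)
    cells[[i]] <- list(label = lab, vertices = v,
                       neighbor_labels = nb, n_neighbors = length(nb),
                       on_border = on_border, area_px = nrow(idx),
                       centroid_px = c(x = mean(idx[, 2]) - 1,
                                       y = mean(idx[, 1]) - 1))
  }
  cells <- cells[!vapply(cells, is.null, logical(1))]
  structure(cells, class = "cell_polygons", dx = dx, dy = dy, mask_dim = dim(mask))
}

#' @export
print.cell_polygons <- function(x, ...) {
  cat(sprintf("<cell_polygons> %d cells (%d touching the border)\n",
              length(x), sum(vapply(x, `[[`, logical(1), "on_border"))))
  invisible(x)
}

# 4-connected component labelling of the non-zero pixels (two-pass
# union-find).
label_components <- function(binary) {
  ny <- nrow(binary); nx <- ncol(binary)
  lab <- matrix(0L, ny, nx)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nextlab <- 0L
  for (j in seq_len(nx)) for (i in seq_len(ny)) {
    if (binary[i, j] == 0) next
    up <- if (i > 1L) lab[i - 1L, j] else 0L
    left <- if (j > 1L) lab[i, j - 1L] else 0L
    if (up == 0L && left == 0L) {
      nextlab <- nextlab + 1L
      parent[nextlab] <- nextlab
      lab[i, j] <- nextlab
    } else if (up == 0L || left == 0L) {
      lab[i, j] <- max(up, left)
    } else {
      lab[i, j] <- min(ru <- find(up), rl <- find(left))
      parent[max(ru, rl)] <- min(ru, rl)
    }
  }
  if (nextlab == 0L) return(lab)
  roots <- vapply(seq_len(nextlab), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  nz <- lab > 0L
  lab[nz] <- relab[lab[nz]]
  lab
}

# Region adjacency: labels touching within a Chebyshev distance `reach`.
label_adjacency <- function(mask, reach = 2L) {
  offs <- expand.grid(di = 0:reach, dj = (-reach):reach)
  offs <- offs[offs$di > 0L | offs$dj > 0L, ]
  ny <- nrow(mask); nx <- ncol(mask)
  pairs <- list()
  for (k in seq_len(nrow(offs))) {
    di <- offs$di[k]; dj <- offs$dj[k]
    ri <- seq_len(ny - di)
    cj <- if (dj >= 0L) seq_len(nx - dj) else seq(1L - dj, nx)
    a <- mask[ri, cj, drop = FALSE]
    b <- mask[ri + di, cj + dj, drop = FALSE]
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) pairs[[length(pairs) + 1L]] <- cbind(a[sel], b[sel])
  }
  if (length(pairs) == 0L) return(list())
  pr <- unique(do.call(rbind, pairs))
  pr <- rbind(pr, pr[, 2:1, drop = FALSE])
  split(pr[, 2], as.character(pr[, 1])) |> lapply(function(v) sort(unique(v)))
}

# --- polygon geometry -------------------------------------------------------

# Signed area (shoelace) of an open 2D ring; > 0 for CCW.
poly_signed_area <- function(xy) {
  n <- nrow(xy)
  i2 <- c(2:n, 1L)
  sum(xy[, 1] * xy[i2, 2] - xy[i2, 1] * xy[, 2]) / 2
}

# Perimeter of a closed ring given as open vertex list (2D or 3D).
poly_perimeter <- function(v) {
  n <- nrow(v)
  d <- v[c(2:n, 1L), , drop = FALSE] - v
  sum(sqrt(rowSums(d^2)))
}

# Area, centroid and central second moments of a 2D polygon interior.
poly_moments <- function(xy) {
  if (poly_signed_area(xy) < 0) xy <- xy[rev(seq_len(nrow(xy))), , drop = FALSE]
  n <- nrow(xy)
  i2 <- c(2:n, 1L)
  x <- xy[, 1]; y <- xy[, 2]
  cr <- x * y[i2] - x[i2] * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100)
    return(list(area = 0, cx = mean(x), cy = mean(y),
                mxx = 0, myy = 0, mxy = 0))
  cx <- sum((x + x[i2]) * cr) / (6 * a)
  cy <- sum((y + y[i2]) * cr) / (6 * a)
  # second moments about the origin
  sxx <- sum((x^2 + x * x[i2] + x[i2]^2) * cr) / 12
  syy <- sum((y^2 + y * y[i2] + y[i2]^2) * cr) / 12
  sxy <- sum((x * y[i2] + 2 * x * y + 2 * x[i2] * y[i2] + x[i2] * y) * cr) / 24
  list(area = a, cx = cx, cy = cy,
       mxx = sxx - a * cx^2, myy = syy - a * cy^2, mxy = sxy - a * cx * cy)
}

#' Lift a 2D polygon onto the reference surface
#'
#' Each vertex (x, y) becomes (x, y, f(x, y)); ordering is preserved. Grid
#' surfaces clamp evaluation outside their domain to the border (with a
#' warning).
#'
#' @param xy n x 2 vertex matrix in micrometres, or a cell from
#'   [mask_to_polygons()].
#' @param surface a `reference_surface`.
#' @return n x 3 matrix (x, y, z) in micrometres.
#' @export
lift_polygon <- function(xy, surface) {
  if (is.list(xy) && !is.null(xy$vertices)) xy <- xy$vertices
  stopifnot(is.matrix(xy), ncol(xy) == 2L,
            inherits(surface, "reference_surface"))
  if (surface$kind == "grid" &&
      (any(xy[, 1] < 0) || any(xy[, 1] > surface$xmax) ||
       any(xy[, 2] < 0) || any(xy[, 2] > surface$ymax)))
    warning("polygon vertices outside the surface domain were clamped")
  cbind(xy, z = surface_height(surface, xy[, 1], xy[, 2]))
}

#' 3D polygon area (oriented centroid-fan triangulation)
#'
#' The contour is triangulated as a fan about its vertex centroid and the
#' triangle areas are summed with a consistent orientation: each triangle
#' counts positively or negatively according to the sign of its cross
#' product against the contour's total vector area. This makes the measure
#' exact for every planar simple polygon — including the locally concave
#' staircase contours produced by pixel tracing, where summing unsigned
#' triangle magnitudes would overestimate — while still responding to
#' out-of-plane deformation of the contour.
#'
#' @param contour3d n x 3 vertex matrix (um).
#' @return area in um^2 (0, with a warning, for degenerate contours).
#' @export
polygon_area_3d <- function(contour3d) {
  stopifnot(is.matrix(contour3d), ncol(contour3d) == 3L)
  n <- nrow(contour3d)
  if (n < 3L) stop("a polygon needs at least 3 vertices")
  ctr <- colMeans(contour3d)
  a <- sweep(contour3d, 2L, ctr)
  b <- a[c(2:n, 1L), , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  tot <- c(sum(cx), sum(cy), sum(cz))
  mag <- sqrt(cx^2 + cy^2 + cz^2)
  sgn <- sign(cx * tot[1] + cy * tot[2] + cz * tot[3])
  area <- abs(sum(sgn * mag)) / 2
  if (area == 0) warning("degenerate (collinear) contour; area is 0")
  area
}

#' 3D polygon perimeter
#'
#' Sum of Euclidean edge lengths over the closed contour.
#'
#' @inheritParams polygon_area_3d
#' @return perimeter in um.
#' @export
polygon_perimeter_3d <- function(contour3d) {
  stopifnot(is.matrix(contour3d), ncol(contour3d) == 3L, nrow(contour3d) >= 3L)
  poly_perimeter(contour3d)
}

#' Fit the apical plane of a 3D contour
#'
#' Total-least-squares plane through the vertices: the normal is the
#' eigenvector of the smallest eigenvalue of the vertex covariance about
#' the centroid, oriented with a positive z component. The slope is the
#' angle between the fitted plane and the XY image plane,
#' `acos(|n_z|)` in degrees. Euler angles use the Z-X'-Z'' convention for
#' the rotation taking the world axes onto the in-plane frame (u, v, n).
#'
#' @inheritParams polygon_area_3d
#' @return list with `normal` (unit length), `slope_theta` (degrees, in
#'   \[0, 90\]), `euler` (alpha, beta, gamma in degrees), `centroid`, and
#'   the in-plane basis `u`, `v`.
#' @export
fit_cell_plane <- function(contour3d) {
  stopifnot(is.matrix(contour3d), ncol(contour3d) == 3L)
  n <- nrow(contour3d)
  if (n < 3L) stop("a plane fit needs at least 3 vertices")
  ctr <- colMeans(contour3d)
  a <- sweep(contour3d, 2L, ctr)
  cv <- crossprod(a) / n
  eg <- eigen(cv, symmetric = TRUE)
  if (eg$values[2] < 1e-12 * max(1, eg$values[1]))
    stop("degenerate geometry: contour vertices are collinear")
  nrm <- eg$vectors[, 3L]
  if (nrm[3] < 0) nrm <- -nrm
  slope <- acos(min(1, abs(nrm[3]))) * 180 / pi
  # deterministic in-plane basis: u = projection of world x unless parallel
  seed_axis <- if (abs(nrm[1]) < 0.99) c(1, 0, 0) else c(0, 1, 0)
  u <- seed_axis - sum(seed_axis * nrm) * nrm
  u <- u / sqrt(sum(u^2))
  v <- c(nrm[2] * u[3] - nrm[3] * u[2],
         nrm[3] * u[1] - nrm[1] * u[3],
         nrm[1] * u[2] - nrm[2] * u[1])
  R <- cbind(u, v, nrm)
  euler <- euler_zxz(R)
  list(normal = nrm, slope_theta = slope, euler = euler,
       centroid = ctr, u = u, v = v)
}

# Z-X'-Z'' Euler angles (degrees) of rotation matrix R = Rz(a) Rx(b) Rz(g).
euler_zxz <- function(R) {
  beta <- acos(min(1, max(-1, R[3, 3])))
  if (sin(beta) > 1e-9) {
    alpha <- atan2(R[1, 3], -R[2, 3])
    gamma <- atan2(R[3, 1], R[3, 2])
  } else {
    alpha <- atan2(R[2, 1], R[1, 1])
    gamma <- 0
  }
  c(alpha = alpha, beta = beta, gamma = gamma) * 180 / pi
}

#' Moment-equivalent ellipse of a cell in its apical plane
#'
#' The contour is projected into the fitted plane's 2D frame and the unique
#' ellipse with the same area and second-order area moments as the polygon
#' interior is computed. Measuring in-plane (rather than on the XY
#' projection) removes the foreshortening of tilted cells.
#'
#' @inheritParams polygon_area_3d
#' @param plane a fit from [fit_cell_plane()]; computed if missing.
#' @return list with `semi_axes` (a >= b, um), `orientation` (degrees of the
#'   major axis in the plane frame, in (-90, 90\]), `eccentricity`
#'   (`sqrt(1 - (b/a)^2)`, in \[0, 1)).
#' @export
fit_ellipse_3d <- function(contour3d, plane = NULL) {
  if (is.null(plane)) plane <- fit_cell_plane(contour3d)
  a <- sweep(contour3d, 2L, plane$centroid)
  p2 <- cbind(a %*% plane$u, a %*% plane$v)
  fit_ellipse_2d(p2)
}

# Moment-equivalent ellipse of a 2D polygon.
fit_ellipse_2d <- function(xy) {
  mo <- poly_moments(xy)
  if (mo$area <= 0) stop("degenerate polygon: cannot fit an ellipse")
  cv <- matrix(c(mo$mxx, mo$mxy, mo$mxy, mo$myy), 2L) / mo$area
  eg <- eigen(cv, symmetric = TRUE)
  ax <- 2 * sqrt(pmax(eg$values, 0))
  if (ax[2] <= 0) stop("degenerate polygon: cannot fit an ellipse")
  vec <- eg$vectors[, 1L]
  ang <- atan2(vec[2], vec[1]) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  list(semi_axes = c(a = ax[1], b = ax[2]),
       orientation = ang,
       eccentricity = sqrt(max(0, 1 - (ax[2] / ax[1])^2)))
}
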