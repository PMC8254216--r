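# Deprojection: combine a 2D segmentation with the reference surface to
# obtain per-cell 3D contours and distortion-corrected morphometrics.

#' Build the deprojection reference surface from a height-map
#'
#' Convenience wrapper around [reference_surface()]: Gaussian-smooths the
#' height-map with a sigma equal to the median cell diameter (to suppress
#' the staircase of integer slice positions) and converts to micrometres.
#'
#' @param hm height-map matrix (1-based slice indices).
#' @param median_cell_diameter smoothing sigma in micrometres.
#' @param dx,dy,dz voxel calibration in micrometres.
#' @return a `reference_surface`.
#' @export
build_reference_surface <- function(hm, median_cell_diameter, dx, dy, dz) {
  if (!is.finite(median_cell_diameter) || median_cell_diameter <= 0)
    stop("'median_cell_diameter' must be > 0")
  reference_surface(hm, dx = dx, dy = dy, dz = dz,
                    sigma_um = median_cell_diameter)
}

#' Deproject a 2D segmentation onto the tissue surface
#'
#' Lifts every cell polygon onto the reference surface and measures, per
#' cell: 2D and 3D area and perimeter, the relative projection errors
#' `e_a = 1 - a2D/a3D` and `e_l = 1 - l2D/l3D`, the apical-plane fit
#' (normal, slope against XY, Z-X'-Z'' Euler angles), the moment-equivalent
#' ellipse both in the apical plane and on the XY projection, neighbour
#' counts, and the local mean/Gaussian curvature of the surface at the cell
#' centroid. Cells touching the image border keep their metrics but are
#' flagged (`on_border`) and excluded from `summary()` statistics.
#'
#' @param mask label mask matrix (or binary junction mask), the 2D
#'   segmentation; alternatively pass `polygons` directly.
#' @param hm height-map matrix with the mask's (y, x) extent (ignored when
#'   `surface` is given).
#' @param dx,dy,dz voxel calibration in micrometres.
#' @param median_cell_diameter smoothing sigma in micrometres, or `"auto"`
#'   (median of the cells' equivalent-area diameters estimated from the
#'   mask).
#' @param surface optionally a ready-made `reference_surface` (e.g. an
#'   analytic surface); skips height-map smoothing.
#' @param polygons optionally a `cell_polygons` object replacing `mask`.
#' @return an object of class `deproj`: list with `cells` (one data.frame
#'   row per cell), `contours` (named list of n x 3 matrices), `surface`,
#'   `sigma_um` and the calibration.
#' @export
deproject <- function(mask = NULL, hm = NULL, dx = 1, dy = 1, dz = 1,
                      median_cell_diameter = "auto", surface = NULL,
                      polygons = NULL) {
  check_calibration(dx, dy, dz)
  if (is.null(polygons)) {
    if (is.null(mask)) stop("provide 'mask' or 'polygons'")
    if (!is.null(hm) && (nrow(hm) != nrow(mask) || ncol(hm) != ncol(mask)))
      stop("mask and height-map extents differ")
    polygons <- mask_to_polygons(mask, dx = dx, dy = dy)
  }
  if (length(polygons) == 0L) stop("no cells found in the segmentation")
  diam_um <- vapply(polygons, function(p)
    2 * sqrt(p$area_px * dx * dy / pi), numeric(1))
  sigma_um <- if (identical(median_cell_diameter, "auto"))
    stats::median(diam_um) else median_cell_diameter
  if (is.null(surface)) {
    if (is.null(hm)) stop("provide 'hm' or 'surface'")
    surface <- build_reference_surface(hm, sigma_um, dx, dy, dz)
  }
  n <- length(polygons)
  contours <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- polygons[[i]]
    v2 <- cell$vertices
    c3 <- lift_polygon(v2, surface)
    contours[[i]] <- c3
    a2 <- abs(poly_signed_area(v2))
    l2 <- poly_perimeter(v2)
    a3 <- polygon_area_3d(c3)
    l3 <- polygon_perimeter_3d(c3)
    pl <- fit_cell_plane(c3)
    el <- fit_ellipse_3d(c3, pl)
    el2 <- fit_ellipse_2d(v2)
    ctr3 <- c(mean(c3[, 1]), mean(c3[, 2]), mean(c3[, 3]))
    cv <- surface_curvature(surface, ctr3[1], ctr3[2])
    rows[[i]] <- data.frame(
      label = cell$label,
      area_2d = a2, area_3d = a3, perim_2d = l2, perim_3d = l3,
      err_area = 1 - a2 / a3, err_perim = 1 - l2 / l3,
      centroid_x = ctr3[1], centroid_y = ctr3[2], centroid_z = ctr3[3],
      normal_x = pl$normal[1], normal_y = pl$normal[2],
      normal_z = pl$normal[3],
      slope_theta = pl$slope_theta,
      euler_alpha = pl$euler[1], euler_beta = pl$euler[2],
      euler_gamma = pl$euler[3],
      ellipse_a = el$semi_axes[1], ellipse_b = el$semi_axes[2],
      ellipse_orientation = el$orientation,
      eccentricity = el$eccentricity,
      orientation_xy = el2$orientation,
      eccentricity_xy = el2$eccentricity,
      n_neighbors = cell$n_neighbors,
      mean_curvature = cv$mean_curvature,
      gaussian_curvature = cv$gaussian_curvature,
      on_border = cell$on_border,
      row.names = NULL)
  }
  cells <- do.call(rbind, rows)
  names(contours) <- cells$label
  structure(list(cells = cells, contours = contours, surface = surface,
                 sigma_um = sigma_um, dx = dx, dy = dy, dz = dz),
            class = "deproj")
}

#' @export
print.deproj <- function(x, ...) {
  cat(sprintf("<deproj> %d cells (%d interior), smoothing sigma %.3g um\n",
              nrow(x$cells), sum(!x$cells$on_border), x$sigma_um))
  cat(sprintf("  median e_a = %.3g, median slope = %.3g deg (interior cells)\n",
              stats::median(x$cells$err_area[!x$cells$on_border]),
              stats::median(x$cells$slope_theta[!x$cells$on_border])))
  invisible(x)
}

#' Summary statistics of a deprojection (interior cells)
#'
#' @param object a `deproj` result.
#' @param ... unused.
#' @return data.frame of mean, sd and median for the main metrics, computed
#'   over cells not touching the image border.
#' @export
summary.deproj <- function(object, ...) {
  cells <- object$cells[!object$cells$on_border, , drop = FALSE]
  metrics <- c("area_2d", "area_3d", "perim_2d", "perim_3d", "err_area",
               "err_perim", "slope_theta", "eccentricity", "n_neighbors",
               "mean_curvature", "gaussian_curvature")
  out <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(cells[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) stats::sd(cells[[m]]), numeric(1)),
    median = vapply(metrics, function(m) stats::median(cells[[m]]), numeric(1)),
    row.names = NULL)
  attr(out, "n_cells") <- nrow(cells)
  out
}

#' Map of a per-cell metric over the tissue
#'
#' Draws the cell polygons filled by the value of one metric column, a
#' plain-graphics analogue of the usual error/slope/curvature maps.
#'
#' @param x a `deproj` result.
#' @param metric column of `x$cells` to map.
#' @param palette colour ramp function (n -> colours).
#' @param ... passed to [graphics::plot()].
#' @export
plot.deproj <- function(x, metric = "err_area",
                        palette = grDevices::hcl.colors, ...) {
  vals <- x$cells[[metric]]
  if (is.null(vals)) stop("unknown metric: ", metric)
  cols <- palette(100L)
  rng <- range(vals, finite = TRUE)
  idx <- if (diff(rng) == 0) rep(1L, length(vals)) else
    pmax(1L, pmin(100L, 1L + floor(99 * (vals - rng[1]) / diff(rng))))
  xs <- unlist(lapply(x$contours, function(v) v[, 1]))
  ys <- unlist(lapply(x$contours, function(v) v[, 2]))
  graphics::plot(NA, xlim = range(xs), ylim = rev(range(ys)), asp = 1,
                 xlab = "x (um)", ylab = "y (um)",
                 main = sprintf("%s [%.3g, %.3g]", metric, rng[1], rng[2]), ...)
  for (i in seq_along(x$contours))
    graphics::polygon(x$contours[[i]][, 1], x$contours[[i]][, 2],
                      col = cols[idx[i]], border = "grey30", lwd = 0.3)
  invisible(x)
}

#' Height-map sensitivity of the 3D measurements
#'
#' Reproduces the robustness probe for erroneous height-maps: for each cell,
#' half of the 3D contour vertices are moved up by one z step while the
#' other half stay in place, and the 3D area and perimeter are recomputed.
#' By default the moved half is one contiguous boundary arc with a
#' uniformly random start (`vertices = "block"`), which emulates a locally
#' wrong height-map deforming one side of the cell; `vertices = "random"`
#' instead scatters the moved vertices along the boundary, which with
#' pixel-dense contours produces a much harsher zig-zag perturbation.
#'
#' @param dp a `deproj` result (or a list of n x 3 contours).
#' @param dz_slice z step in micrometres (one slice).
#' @param seed integer seed for the random choice of moved vertices.
#' @param vertices `"block"` (contiguous arc) or `"random"` (scattered).
#' @return an object of class `contour_perturbation`: data.frame `cells`
#'   with per-cell relative differences, and `summary` with mean and sd of
#'   the relative area and perimeter differences.
#' @export
perturb_contours <- function(dp, dz_slice, seed = NULL,
                             vertices = c("block", "random")) {
  vertices <- match.arg(vertices)
  if (!is.finite(dz_slice) || dz_slice < 0)
    stop("'dz_slice' must be a non-negative z step in micrometres")
  contours <- if (inherits(dp, "deproj")) dp$contours else dp
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (i in seq_along(contours)) {
    c3 <- contours[[i]]
    n <- nrow(c3)
    if (n < 4L) {
      warning(sprintf("contour %d has fewer than 4 vertices; skipped", i))
      next
    }
    m <- n %/% 2L
    idx <- if (vertices == "block") {
      start <- sample.int(n, 1L)
      ((start - 1L + seq_len(m) - 1L) %% n) + 1L
    } else {
      sample.int(n, m)
    }
    p3 <- c3
    p3[idx, 3] <- p3[idx, 3] + dz_slice
    a0 <- polygon_area_3d(c3); a1 <- polygon_area_3d(p3)
    l0 <- polygon_perimeter_3d(c3); l1 <- polygon_perimeter_3d(p3)
    rows[[length(rows) + 1L]] <- data.frame(
      cell = i, area_3d = a0, area_3d_perturbed = a1,
      perim_3d = l0, perim_3d_perturbed = l1,
      rel_area_diff = abs(a1 - a0) / a0,
      rel_perim_diff = abs(l1 - l0) / l0)
  }
  cells <- do.call(rbind, rows)
  structure(list(
    cells = cells,
    summary = list(
      dz_slice = dz_slice, vertices = vertices,
      mean_rel_area_diff = mean(cells$rel_area_diff),
      sd_rel_area_diff = stats::sd(cells$rel_area_diff),
      mean_rel_perim_diff = mean(cells$rel_perim_diff),
      sd_rel_perim_diff = stats::sd(cells$rel_perim_diff))),
    class = "contour_perturbation")
}

#' @export
print.contour_perturbation <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<contour_perturbation> %d cells, dz = %.3g um (%s half)\n",
              nrow(x$cells), s$dz_slice, s$vertices))
  cat(sprintf("  relative area difference:      %.2f +/- %.2f %%\n",
              100 * s$mean_rel_area_diff, 100 * s$sd_rel_area_diff))
  cat(sprintf("  relative perimeter difference: %.2f +/- %.2f %%\n",
              100 * s$mean_rel_perim_diff, 100 * s$sd_rel_perim_diff))
  invisible(x)
}
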