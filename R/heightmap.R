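# Reference-surface (height-map) extraction.
#
# The epithelial layer is located, per (x, y) position, as the z slice where
# a 2D response filter (windowed mean or windowed standard deviation,
# optionally after Gaussian pre-smoothing) is strongest. Planes can be
# block-binned first; the raw argmax map is then regularised with a large
# median filter (still in binned space) and rescaled bilinearly to the full
# image extent, so values may be fractional.

#' Height-map extraction parameters
#'
#' Defaults follow the settings that work well on notum-like volumes: a
#' standard-deviation filter of window 21 x 21, 2 x 2 binning, no Gaussian
#' pre-smoothing and a 21 x 21 median regularisation.
#'
#' @param filter_kind `"std"` (windowed standard deviation, responds to
#'   membrane texture) or `"mean"` (windowed mean, responds to bright
#'   sheets).
#' @param filter_window odd integer side of the response filter window, in
#'   binned pixels.
#' @param binning integer block-binning factor applied to each plane before
#'   filtering (>= 1).
#' @param presmooth_sigma Gaussian pre-smoothing sigma in binned pixels
#'   (0 disables), applied to the binned plane before the response filter.
#' @param median_window odd integer side of the median regularisation
#'   window, in binned pixels (1 disables).
#' @param target_channel channel used to extract the surface.
#' @return an object of class `height_map_params`.
#' @export
height_map_params <- function(filter_kind = c("std", "mean"),
                              filter_window = 21L, binning = 2L,
                              presmooth_sigma = 0, median_window = 21L,
                              target_channel = 1L) {
  filter_kind <- match.arg(filter_kind)
  check_odd_window(filter_window, "filter_window")
  check_odd_window(median_window, "median_window")
  binning <- as.integer(binning)
  if (is.na(binning) || binning < 1L) stop("'binning' must be an integer >= 1")
  if (!is.finite(presmooth_sigma) || presmooth_sigma < 0)
    stop("'presmooth_sigma' must be >= 0")
  structure(list(filter_kind = filter_kind,
                 filter_window = as.integer(filter_window),
                 binning = binning,
                 presmooth_sigma = presmooth_sigma,
                 median_window = as.integer(median_window),
                 target_channel = as.integer(target_channel)),
            class = "height_map_params")
}

#' Response of the layer-detection filter on one plane
#'
#' Optional Gaussian smoothing followed by the windowed mean or windowed
#' population standard deviation. A constant plane has zero std response
#' everywhere; the mean response of a constant plane is that constant.
#'
#' @param plane numeric matrix.
#' @param kind `"mean"` or `"std"`.
#' @param window odd integer window side.
#' @param presmooth_sigma Gaussian sigma in pixels, 0 to disable.
#' @return response matrix, same size as `plane`.
#' @export
plane_response <- function(plane, kind = c("std", "mean"), window = 21L,
                           presmooth_sigma = 0) {
  kind <- match.arg(kind)
  if (presmooth_sigma > 0) plane <- gaussian_smooth(plane, presmooth_sigma)
  window_filter(plane, window, kind)
}

#' Extract the height-map of a stack
#'
#' For every binned (y, x) position the height-map holds the z slice that
#' maximises the filter response (ties broken toward the smallest z, i.e.
#' the slice closest to the objective). The argmax map is median-regularised
#' in binned space and rescaled to the full stack extent.
#'
#' @param stack a `volume_stack`.
#' @param params a [height_map_params()] object.
#' @param timepoint which timepoint to process.
#' @return numeric matrix of (possibly fractional) 1-based slice indices,
#'   same (y, x) extent as the stack.
#' @export
extract_height_map <- function(stack, params = height_map_params(),
                               timepoint = 1L) {
  stopifnot(inherits(stack, "volume_stack"),
            inherits(params, "height_map_params"))
  if (stack$nz < 1L) stop("empty stack: no z slices")
  if (params$target_channel < 1L || params$target_channel > stack$nc)
    stop("target_channel out of range")
  best <- NULL
  arg <- NULL
  for (z in seq_len(stack$nz)) {
    p <- get_plane(stack, params$target_channel, z, timepoint)
    p <- bin_plane(p, params$binning)
    r <- plane_response(p, params$filter_kind, params$filter_window,
                        params$presmooth_sigma)
    if (is.null(best)) {
      best <- r
      arg <- matrix(1, nrow(r), ncol(r))
    } else {
      upd <- r > best          # strict: ties keep the smaller z
      arg[upd] <- z
      best[upd] <- r[upd]
    }
  }
  hm <- regularize_height_map(arg, params$median_window)
  rescale_height_map(hm, params$binning, c(stack$ny, stack$nx))
}

#' Median-regularise a height-map
#'
#' Removes localised argmax outliers (e.g. bright fat-body spots captured
#' below the layer) with a per-pixel median over a large window. The output
#' value range is contained in the input range, and constant maps are left
#' unchanged.
#'
#' @param hm height-map matrix.
#' @param median_window odd integer window side (1 = no-op).
#' @return regularised height-map.
#' @export
regularize_height_map <- function(hm, median_window) {
  stopifnot(is.matrix(hm))
  median_filter(hm, median_window)
}

#' Rescale a binned height-map to the full image extent
#'
#' Bilinear interpolation between binned block centres; a binned pixel
#' `(i, j)` (1-based) is taken to sit at full-resolution position
#' `((i - 1) * b + (b - 1) / 2)` along each axis. Positions beyond the
#' outermost block centres are clamped. With `b = 1` and matching shape this
#' is the identity.
#'
#' @param hm binned height-map.
#' @param b binning factor used at extraction.
#' @param target_shape `c(ny, nx)` of the output.
#' @return height-map matrix of dimension `target_shape`; values may be
#'   fractional.
#' @export
rescale_height_map <- function(hm, b, target_shape) {
  stopifnot(is.matrix(hm), length(target_shape) == 2L)
  b <- as.integer(b)
  if (is.na(b) || b < 1L) stop("'b' must be an integer >= 1")
  ny <- target_shape[1]; nx <- target_shape[2]
  if (b == 1L) {
    if (ny == nrow(hm) && nx == ncol(hm)) return(hm)
    if (ny < nrow(hm) || nx < ncol(hm))
      stop("target shape smaller than source with b = 1")
  }
  # 0-based source coordinates of the target pixel centres
  sy <- (seq_len(ny) - 1 - (b - 1) / 2) / b
  sx <- (seq_len(nx) - 1 - (b - 1) / 2) / b
  row0 <- matrix(sy, ny, nx)
  col0 <- matrix(sx, ny, nx, byrow = TRUE)
  matrix(bilinear_sample(hm, row0, col0), ny, nx)
}
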