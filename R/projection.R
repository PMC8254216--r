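# Local Z projection: collect intensity around the reference surface.

#' Per-channel projection parameters
#'
#' Intensity for a channel is accumulated over slices
#' `z* + offset - delta_z ... z* + offset + delta_z`, where `z*` is the
#' rounded height-map value at the pixel; the window is clipped to the valid
#' slice range. An offset lets a channel be collected above or below the
#' reference surface (e.g. nuclei a few micrometres under the junction
#' plane).
#'
#' @param offset signed integer slice offset relative to the reference
#'   surface.
#' @param delta_z integer half-range of accumulated slices (>= 0); 0 reads a
#'   single slice.
#' @param mode `"max"` or `"mean"` accumulation over the window.
#' @return an object of class `channel_params`.
#' @export
channel_params <- function(offset = 0L, delta_z = 0L, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  offset <- as.integer(offset); delta_z <- as.integer(delta_z)
  if (is.na(delta_z) || delta_z < 0L) stop("'delta_z' must be an integer >= 0")
  if (is.na(offset)) stop("'offset' must be an integer")
  structure(list(offset = offset, delta_z = delta_z, mode = mode),
            class = "channel_params")
}

# Round half-up (fractional height-map values to slice indices).
round_half_up <- function(x) floor(x + 0.5)

#' Project one channel around a height-map
#'
#' @param stack a `volume_stack`.
#' @param channel channel index.
#' @param hm height-map matrix (1-based, possibly fractional slice indices)
#'   with the stack's (y, x) extent.
#' @param params a [channel_params()] object.
#' @param timepoint timepoint index.
#' @return projected 2D intensity matrix.
#' @details The accumulation window is clipped at the stack boundaries and
#'   the mean divides by the number of slices actually used. A window that
#'   falls entirely outside the stack collapses to the nearest valid slice.
#'   Each required plane is read exactly once.
#' @export
project_channel <- function(stack, channel = 1L, hm,
                            params = channel_params(), timepoint = 1L) {
  stopifnot(inherits(stack, "volume_stack"),
            inherits(params, "channel_params"), is.matrix(hm))
  if (nrow(hm) != stack$ny || ncol(hm) != stack$nx)
    stop(sprintf("height-map extent (%d x %d) does not match stack (%d x %d)",
                 nrow(hm), ncol(hm), stack$ny, stack$nx))
  if (any(!is.finite(hm))) stop("height-map contains non-finite values")
  zc <- round_half_up(hm) + params$offset
  zlo <- pmax(1, zc - params$delta_z)
  zhi <- pmin(stack$nz, zc + params$delta_z)
  # window entirely outside the stack: collapse to the nearest valid slice
  oob <- zlo > zhi
  if (any(oob)) {
    znear <- pmin(stack$nz, pmax(1, zc[oob]))
    zlo[oob] <- znear
    zhi[oob] <- znear
  }
  zrange <- seq(min(zlo), max(zhi))
  if (params$mode == "max") {
    out <- matrix(-Inf, stack$ny, stack$nx)
  } else {
    out <- matrix(0, stack$ny, stack$nx)
    cnt <- matrix(0L, stack$ny, stack$nx)
  }
  for (z in zrange) {
    sel <- zlo <= z & z <= zhi
    if (!any(sel)) next
    p <- get_plane(stack, channel, z, timepoint)
    if (params$mode == "max") {
      out[sel] <- pmax(out[sel], p[sel])
    } else {
      out[sel] <- out[sel] + p[sel]
      cnt[sel] <- cnt[sel] + 1L
    }
  }
  if (params$mode == "mean") out <- out / cnt
  out
}

#' Two-pass local projection of a whole stack
#'
#' Pass one extracts the height-map from the target channel; pass two
#' projects every channel around it. Timepoints are processed independently
#' and in order, each with its own height-map (no temporal smoothing). On a
#' streamed stack no plane is ever read more than twice: once during surface
#' extraction (target channel only) and once during projection.
#'
#' @param stack a `volume_stack`.
#' @param hm_params a [height_map_params()] object.
#' @param proj_params a single [channel_params()] (recycled over channels)
#'   or a list with one `channel_params` per channel.
#' @return an object of class `local_projection` with fields `images`
#'   (list over timepoints of lists over channels), `height_maps` (list over
#'   timepoints), `hm_params` and `proj_params`.
#' @export
project_stack <- function(stack, hm_params = height_map_params(),
                          proj_params = channel_params()) {
  stopifnot(inherits(stack, "volume_stack"))
  if (inherits(proj_params, "channel_params"))
    proj_params <- rep(list(proj_params), stack$nc)
  if (length(proj_params) != stack$nc ||
      !all(vapply(proj_params, inherits, logical(1), "channel_params")))
    stop("'proj_params' must be one channel_params per channel")
  images <- vector("list", stack$nt)
  hms <- vector("list", stack$nt)
  for (t in seq_len(stack$nt)) {
    hm <- extract_height_map(stack, hm_params, timepoint = t)
    hms[[t]] <- hm
    images[[t]] <- lapply(seq_len(stack$nc), function(c)
      project_channel(stack, c, hm, proj_params[[c]], timepoint = t))
  }
  structure(list(images = images, height_maps = hms,
                 hm_params = hm_params, proj_params = proj_params,
                 dx = stack$dx, dy = stack$dy, dz = stack$dz),
            class = "local_projection")
}

#' Extract one projected image from a `local_projection`
#' @param proj a `local_projection`.
#' @param channel,timepoint indices.
#' @return 2D intensity matrix.
#' @export
projection_image <- function(proj, channel = 1L, timepoint = 1L) {
  stopifnot(inherits(proj, "local_projection"))
  proj$images[[timepoint]][[channel]]
}

#' @export
print.local_projection <- function(x, ...) {
  nt <- length(x$images); nc <- length(x$images[[1]])
  d <- dim(x$images[[1]][[1]])
  cat(sprintf("<local_projection> %d x %d px, %d channel(s), %d timepoint(s)\n",
              d[1], d[2], nc, nt))
  cat(sprintf("  height-map filter: %s, window %d, binning %d, median %d\n",
              x$hm_params$filter_kind, x$hm_params$filter_window,
              x$hm_params$binning, x$hm_params$median_window))
  invisible(x)
}
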