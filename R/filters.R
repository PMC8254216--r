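# 2D filter primitives used by the height-map pipeline.
#
# All sliding filters use symmetric (reflective, edge-included) border
# padding so that outputs keep the input size. Windows must be odd so the
# filter is centred.

#' Block-bin a 2D plane
#'
#' Reduces a plane by averaging non-overlapping `b` x `b` blocks. Edge
#' blocks that do not fit completely are averaged over the pixels they do
#' contain, so the output is `ceiling(ny/b)` x `ceiling(nx/b)`. Binning by
#' mean (rather than decimation) suppresses pixel noise before the response
#' filter runs, at the cost of lateral resolution.
#'
#' @param plane numeric matrix (y by x).
#' @param b integer binning factor, >= 1. `b = 1` returns the input
#'   unchanged.
#' @return numeric matrix of block means.
#' @export
bin_plane <- function(plane, b) {
  stopifnot(is.matrix(plane))
  b <- as.integer(b)
  if (length(b) != 1L || is.na(b) || b < 1L)
    stop("binning factor 'b' must be a single integer >= 1")
  if (b == 1L) return(plane)
  iy <- rep(seq_len(ceiling(nrow(plane) / b)), each = b)[seq_len(nrow(plane))]
  ix <- rep(seq_len(ceiling(ncol(plane) / b)), each = b)[seq_len(ncol(plane))]
  sums <- rowsum(plane, iy, reorder = TRUE)
  sums <- t(rowsum(t(sums), ix, reorder = TRUE))
  counts <- tabulate(iy) %o% tabulate(ix)
  unname(sums / counts)
}

# Symmetric (edge-included) padding by ry rows and rx columns on each side.
pad_symmetric <- function(m, ry, rx = ry) {
  ny <- nrow(m); nx <- ncol(m)
  if (ry >= ny || rx >= nx)
    stop("filter window too large for image (padding radius exceeds size)")
  yi <- c(rev(seq_len(ry)), seq_len(ny), ny - seq_len(ry) + 1L)
  xi <- c(rev(seq_len(rx)), seq_len(nx), nx - seq_len(rx) + 1L)
  m[yi, xi, drop = FALSE]
}

check_odd_window <- function(window, what = "window") {
  w <- as.integer(window)
  if (length(w) != 1L || is.na(w) || w < 1L || w %% 2L == 0L)
    stop(sprintf("'%s' must be a single odd integer >= 1", what))
  w
}

#' Sliding-window mean or standard-deviation filter
#'
#' Computes, for every pixel, the mean or the population (1/N) standard
#' deviation of the `window` x `window` neighbourhood, with symmetric border
#' padding. Implemented with integral images, so cost is independent of the
#' window size.
#'
#' @param plane numeric matrix.
#' @param window odd integer window side.
#' @param kind `"mean"` or `"std"`.
#' @return numeric matrix, same size as `plane`.
#' @export
window_filter <- function(plane, window, kind = c("mean", "std")) {
  kind <- match.arg(kind)
  w <- check_odd_window(window, "filter_window")
  if (w == 1L) {
    if (kind == "mean") return(plane)
    return(array(0, dim(plane)))
  }
  r <- (w - 1L) %/% 2L
  p <- pad_symmetric(plane, r)
  n2 <- as.numeric(w) * w
  win_sum <- function(q) {
    cs <- apply(q, 2L, cumsum)
    cs <- t(apply(cs, 1L, cumsum))
    s <- matrix(0, nrow(q) + 1L, ncol(q) + 1L)
    s[-1L, -1L] <- cs
    ny <- nrow(plane); nx <- ncol(plane)
    s[(1L + w):(ny + w), (1L + w):(nx + w)] -
      s[1:ny, (1L + w):(nx + w)] -
      s[(1L + w):(ny + w), 1:nx] +
      s[1:ny, 1:nx]
  }
  m <- win_sum(p) / n2
  if (kind == "mean") return(m)
  msq <- win_sum(p * p) / n2
  sqrt(pmax(msq - m * m, 0))
}

#' Sliding-window median filter
#'
#' Per-pixel median of the `window` x `window` neighbourhood with symmetric
#' border padding. Because the window holds an odd number of samples the
#' median is an element of the input, so integer-valued maps stay
#' integer-valued and the output range never exceeds the input range.
#'
#' @inheritParams window_filter
#' @return filtered matrix, same size as input.
#' @export
median_filter <- function(plane, window) {
  w <- check_odd_window(window, "median_window")
  if (w == 1L) return(plane)
  r <- (w - 1L) %/% 2L
  p <- pad_symmetric(plane, r)
  ny <- nrow(plane); nx <- ncol(plane)
  mid <- (w * w + 1L) %/% 2L
  out <- matrix(NA_real_, ny, nx)
  # process row blocks to bound the (block * nx * w^2) working set
  block <- max(1L, floor(8e6 / (as.numeric(nx) * w * w)))
  i0 <- 1L
  while (i0 <= ny) {
    i1 <- min(ny, i0 + block - 1L)
    nb <- i1 - i0 + 1L
    neigh <- matrix(NA_real_, nb * nx, w * w)
    k <- 0L
    for (dx in 0:(w - 1L)) for (dy in 0:(w - 1L)) {
      k <- k + 1L
      neigh[, k] <- as.vector(p[(i0 + dy):(i1 + dy), dx + seq_len(nx), drop = FALSE])
    }
    out[i0:i1, ] <- matrix(
      apply(neigh, 1L, function(v) sort.int(v, partial = mid)[mid]),
      nb, nx)
    i0 <- i1 + 1L
  }
  out
}

# 1D Gaussian kernel, truncated at ceiling(3*sigma), normalised.
gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

#' Separable Gaussian smoothing of a 2D grid
#'
#' Convolution with a normalised, truncated (3 sigma) Gaussian kernel,
#' symmetric border padding. `sigma <= 0` returns the input unchanged.
#' Distinct sigmas per axis support anisotropic pixel sizes.
#'
#' @param plane numeric matrix.
#' @param sigma standard deviation in pixels; scalar or `c(sigma_y, sigma_x)`.
#' @return smoothed matrix, same size as input.
#' @export
gaussian_smooth <- function(plane, sigma) {
  if (length(sigma) == 1L) sigma <- c(sigma, sigma)
  if (all(sigma <= 0)) return(plane)
  out <- plane
  if (sigma[1] > 0) {
    k <- gaussian_kernel(sigma[1])
    r <- (length(k) - 1L) %/% 2L
    r <- min(r, nrow(out) - 1L)
    k <- gaussian_kernel_clipped(sigma[1], r)
    p <- pad_symmetric(out, r, 0L)
    acc <- matrix(0, nrow(out), ncol(out))
    for (t in seq_along(k))
      acc <- acc + k[t] * p[(t - 1L) + seq_len(nrow(out)), , drop = FALSE]
    out <- acc
  }
  if (sigma[2] > 0) {
    k <- gaussian_kernel(sigma[2])
    r <- (length(k) - 1L) %/% 2L
    r <- min(r, ncol(out) - 1L)
    k <- gaussian_kernel_clipped(sigma[2], r)
    p <- pad_symmetric(out, 0L, r)
    acc <- matrix(0, nrow(out), ncol(out))
    for (t in seq_along(k))
      acc <- acc + k[t] * p[, (t - 1L) + seq_len(ncol(out)), drop = FALSE]
    out <- acc
  }
  out
}

gaussian_kernel_clipped <- function(sigma, r) {
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Bilinear sampling of matrix m at fractional 0-based (row, col) positions.
# Positions are clamped to the grid, so queries outside the domain evaluate
# to the nearest border value.
bilinear_sample <- function(m, row0, col0) {
  ny <- nrow(m); nx <- ncol(m)
  r <- pmin(pmax(row0, 0), ny - 1)
  c <- pmin(pmax(col0, 0), nx - 1)
  r0 <- pmin(floor(r), ny - 2); r0 <- pmax(r0, 0)
  c0 <- pmin(floor(c), nx - 2); c0 <- pmax(c0, 0)
  if (ny == 1L) r0 <- r * 0
  if (nx == 1L) c0 <- c * 0
  fr <- r - r0
  fc <- c - c0
  i00 <- (r0 + 1L) + ny * c0
  i10 <- i00 + (ny > 1L)
  i01 <- i00 + ny * (nx > 1L)
  i11 <- i01 + (ny > 1L)
  m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
}
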