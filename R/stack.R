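# Calibrated multi-channel 3D stacks, eager or streamed (plane-on-demand).
#
# A `volume_stack` stores intensities indexed (y, x, z, channel, timepoint)
# with pixel calibration in micrometres. The only access pattern required by
# the pipeline is random access to a single (channel, z, timepoint) plane;
# streamed stacks provide exactly that through a reader function, keeping at
# most one plane in memory, and every access is counted so the two-pass
# read contract can be verified.

#' Create an in-memory volume stack
#'
#' @param data numeric array with dimensions `(y, x, z)`, `(y, x, z, channel)`
#'   or `(y, x, z, channel, timepoint)`. Intensities must be non-negative.
#' @param dx,dy pixel size in micrometres.
#' @param dz slice spacing in micrometres.
#' @param count_reads if `TRUE`, plane accesses through [get_plane()] are
#'   tallied (always on for streamed stacks).
#' @return an object of class `volume_stack`.
#' @seealso [streamed_stack()], [get_plane()], [read_stack()]
#' @export
volume_stack <- function(data, dx = 1, dy = 1, dz = 1, count_reads = FALSE) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L)
  nd <- length(dim(data))
  if (!is.array(data) || nd < 3L || nd > 5L)
    stop("'data' must be a 3D, 4D or 5D array (y, x, z[, channel[, timepoint]])")
  dim(data) <- c(dim(data), rep(1L, 5L - nd))
  if (any(data < 0, na.rm = TRUE))
    stop("stack intensities must be non-negative")
  check_calibration(dx, dy, dz)
  s <- structure(list(
    ny = dim(data)[1], nx = dim(data)[2], nz = dim(data)[3],
    nc = dim(data)[4], nt = dim(data)[5],
    dx = dx, dy = dy, dz = dz,
    data = data, reader = NULL,
    counts = if (count_reads) new_count_env(dim(data)[4], dim(data)[3], dim(data)[5]) else NULL
  ), class = "volume_stack")
  s
}

#' Create a streamed (plane-on-demand) volume stack
#'
#' The stack never holds more than the plane currently requested; `reader`
#' is called once per access and every access is counted, which makes the
#' "each plane read at most twice" contract of the two-pass projection
#' verifiable with [plane_read_counts()].
#'
#' @param reader function `(channel, z, timepoint) -> matrix` returning one
#'   plane.
#' @param ny,nx,nz plane height, width and slice count.
#' @param nc,nt number of channels and timepoints.
#' @inheritParams volume_stack
#' @return an object of class `volume_stack`.
#' @export
streamed_stack <- function(reader, ny, nx, nz, nc = 1, nt = 1,
                           dx = 1, dy = 1, dz = 1) {
  stopifnot(is.function(reader))
  check_calibration(dx, dy, dz)
  structure(list(
    ny = as.integer(ny), nx = as.integer(nx), nz = as.integer(nz),
    nc = as.integer(nc), nt = as.integer(nt),
    dx = dx, dy = dy, dz = dz,
    data = NULL, reader = reader,
    counts = new_count_env(nc, nz, nt)
  ), class = "volume_stack")
}

new_count_env <- function(nc, nz, nt) {
  e <- new.env(parent = emptyenv())
  e$counts <- array(0L, c(nc, nz, nt))
  e
}

check_calibration <- function(dx, dy, dz) {
  if (any(!is.finite(c(dx, dy, dz))) || any(c(dx, dy, dz) <= 0))
    stop("calibration dx, dy, dz must be positive and finite")
  invisible(TRUE)
}

is_streamed <- function(stack) !is.null(stack$reader)

#' Fetch one plane of a stack
#'
#' @param stack a `volume_stack`.
#' @param channel,z,timepoint 1-based indices.
#' @return numeric matrix `(y, x)`.
#' @export
get_plane <- function(stack, channel = 1L, z, timepoint = 1L) {
  stopifnot(inherits(stack, "volume_stack"))
  if (channel < 1L || channel > stack$nc) stop("invalid channel index")
  if (z < 1L || z > stack$nz) stop("invalid z index")
  if (timepoint < 1L || timepoint > stack$nt) stop("invalid timepoint index")
  if (!is.null(stack$counts))
    stack$counts$counts[channel, z, timepoint] <-
      stack$counts$counts[channel, z, timepoint] + 1L
  if (is_streamed(stack)) {
    p <- stack$reader(channel, z, timepoint)
    if (!is.matrix(p) || nrow(p) != stack$ny || ncol(p) != stack$nx)
      stop(sprintf("streamed reader returned a malformed plane (c=%d, z=%d, t=%d)",
                   channel, z, timepoint))
    p
  } else {
    stack$data[, , z, channel, timepoint]
  }
}

#' Per-plane read counts of an instrumented stack
#'
#' @param stack a `volume_stack` created with `count_reads = TRUE` or via
#'   [streamed_stack()].
#' @return integer array `(channel, z, timepoint)` of access counts.
#' @export
plane_read_counts <- function(stack) {
  stopifnot(inherits(stack, "volume_stack"))
  if (is.null(stack$counts)) stop("stack is not instrumented; no read counts")
  stack$counts$counts
}

#' Reset the read counter of an instrumented stack
#' @inheritParams plane_read_counts
#' @export
reset_plane_counts <- function(stack) {
  stopifnot(inherits(stack, "volume_stack"))
  if (!is.null(stack$counts))
    stack$counts$counts <- array(0L, dim(stack$counts$counts))
  invisible(stack)
}

#' @export
print.volume_stack <- function(x, ...) {
  cat(sprintf("<volume_stack> %d x %d px, %d slices, %d channel(s), %d timepoint(s)%s\n",
              x$ny, x$nx, x$nz, x$nc, x$nt,
              if (is_streamed(x)) " [streamed]" else ""))
  cat(sprintf("  calibration: dx = %g, dy = %g, dz = %g um\n", x$dx, x$dy, x$dz))
  invisible(x)
}

#' @export
dim.volume_stack <- function(x) c(x$ny, x$nx, x$nz, x$nc, x$nt)

#' Maximum intensity projection
#'
#' Per-pixel maximum over all z slices of one channel. This is the baseline
#' projection; it mixes in signal from every layer of the volume, which is
#' exactly what the local projection avoids.
#'
#' @param stack a `volume_stack`.
#' @param channel,timepoint 1-based indices.
#' @return numeric matrix `(y, x)`.
#' @export
mip <- function(stack, channel = 1L, timepoint = 1L) {
  stopifnot(inherits(stack, "volume_stack"))
  out <- get_plane(stack, channel, 1L, timepoint)
  if (stack$nz > 1L)
    for (z in 2:stack$nz)
      out <- pmax(out, get_plane(stack, channel, z, timepoint))
  out
}

# ---------------------------------------------------------------------------
# TIFF I/O.
#
# Reading goes through tiff::readTIFF, which returns 32-bit float samples
# unscaled. Writing float data outside [0, 1] needs a minimal uncompressed
# baseline-TIFF writer, implemented here (single strip per page, little
# endian, SampleFormat = IEEE float).

#' Write matrices as a multi-page 32-bit float TIFF
#'
#' @param images a matrix or list of equally-sized matrices (pages).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tiff_float <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1L, all(vapply(images, is.matrix, logical(1))))
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  entry <- function(tag, type, count, value) {
    u16(tag); u16(type); u32(count)
    if (type == 3L) { u16(value); u16(0L) } else u32(value)
  }
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  writeBin(charToRaw("II"), con); u16(42L)
  u32(8L + nrow(images[[1]]) * ncol(images[[1]]) * 4L)  # first IFD offset
  pos <- 8L
  for (i in seq_along(images)) {
    m <- images[[i]]
    ny <- nrow(m); nx <- ncol(m)
    nbytes <- ny * nx * 4L
    data_off <- pos
    ifd_off <- data_off + nbytes
    # strip data, row-major
    writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
    u16(n_entries)
    entry(256L, 3L, 1L, nx)              # ImageWidth
    entry(257L, 3L, 1L, ny)              # ImageLength
    entry(258L, 3L, 1L, 32L)             # BitsPerSample
    entry(259L, 3L, 1L, 1L)              # Compression: none
    entry(262L, 3L, 1L, 1L)              # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off)        # StripOffsets
    entry(277L, 3L, 1L, 1L)              # SamplesPerPixel
    entry(278L, 3L, 1L, ny)              # RowsPerStrip
    entry(279L, 4L, 1L, nbytes)          # StripByteCounts
    entry(339L, 3L, 1L, 3L)              # SampleFormat: IEEE float
    u32(if (i < length(images))          # next page's IFD sits after its data
      ifd_off + ifd_size + nrow(images[[i + 1L]]) * ncol(images[[i + 1L]]) * 4L
      else 0L)
    pos <- ifd_off + ifd_size
  }
  invisible(path)
}

page_index <- function(c, z, t, nc, nz, axis_order) {
  switch(axis_order,
    XYCZT = ((t - 1L) * nz + (z - 1L)) * nc + c,
    XYZCT = ((t - 1L) * nc + (c - 1L)) * nz + z,
    stop("unsupported axis order: ", axis_order))
}

#' Read a TIFF stack
#'
#' Pages are interpreted with the ImageJ hyperstack convention `XYCZT`
#' (channel varying fastest, then z, then time) unless told otherwise. In
#' streaming mode the file is opened per requested plane and only that page
#' is decoded; eager mode loads all pages at once. Both modes yield
#' identical plane contents.
#'
#' @param path TIFF file.
#' @param n_channels,n_timepoints layout of the pages; the number of slices
#'   is inferred from the page count.
#' @param axis_order `"XYCZT"` (ImageJ default) or `"XYZCT"`.
#' @param streaming read plane-on-demand instead of loading the whole file.
#' @inheritParams volume_stack
#' @return a `volume_stack`.
#' @export
read_stack <- function(path, n_channels = 1L, n_timepoints = 1L,
                       axis_order = c("XYCZT", "XYZCT"), streaming = FALSE,
                       dx = 1, dy = 1, dz = 1) {
  axis_order <- match.arg(axis_order)
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  meta <- tryCatch(tiff::readTIFF(path, all = TRUE, payload = FALSE),
                   error = function(e) stop("unreadable TIFF '", path, "': ",
                                            conditionMessage(e)))
  npages <- nrow(meta)
  nc <- as.integer(n_channels); nt <- as.integer(n_timepoints)
  if (npages %% (nc * nt) != 0L)
    stop(sprintf("page count %d is not divisible by channels x timepoints (%d x %d)",
                 npages, nc, nt))
  nz <- npages %/% (nc * nt)
  ny <- meta$length[1]; nx <- meta$width[1]
  if (streaming) {
    streamed_stack(function(c, z, t) {
      p <- tiff::readTIFF(path, all = page_index(c, z, t, nc, nz, axis_order))[[1]]
      if (!is.matrix(p)) p <- p[, , 1L]
      p
    }, ny, nx, nz, nc, nt, dx, dy, dz)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    pages <- lapply(pages, function(p) if (is.matrix(p)) p else p[, , 1L])
    shapes <- vapply(pages, dim, integer(2))
    if (any(shapes[1, ] != ny) || any(shapes[2, ] != nx))
      stop("inconsistent plane shapes in '", path, "' (plane ",
           which(shapes[1, ] != ny | shapes[2, ] != nx)[1], ")")
    arr <- array(0, c(ny, nx, nz, nc, nt))
    for (t in seq_len(nt)) for (z in seq_len(nz)) for (c in seq_len(nc))
      arr[, , z, c, t] <- pages[[page_index(c, z, t, nc, nz, axis_order)]]
    volume_stack(arr, dx = dx, dy = dy, dz = dz)
  }
}

#' Write a volume stack to a multi-page float TIFF
#'
#' @param stack a `volume_stack` (must be eager or streamable; every plane
#'   is fetched once).
#' @param path output file.
#' @inheritParams read_stack
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, axis_order = c("XYCZT", "XYZCT")) {
  axis_order <- match.arg(axis_order)
  stopifnot(inherits(stack, "volume_stack"))
  pages <- vector("list", stack$nc * stack$nz * stack$nt)
  for (t in seq_len(stack$nt)) for (z in seq_len(stack$nz))
    for (c in seq_len(stack$nc))
      pages[[page_index(c, z, t, stack$nc, stack$nz, axis_order)]] <-
        get_plane(stack, c, z, t)
  write_tiff_float(pages, path)
}

#' Write a height-map to a single-plane float TIFF
#'
#' The file contract stores the z-slice index 0-based (pixel value 0 means
#' the first slice); in R the height-map is 1-based, so the writer subtracts
#' one and [read_height_map()] adds it back.
#'
#' @param hm numeric matrix of 1-based (possibly fractional) slice indices.
#' @param path output file.
#' @export
write_height_map <- function(hm, path) {
  stopifnot(is.matrix(hm))
  write_tiff_float(hm - 1, path)
}

#' @rdname write_height_map
#' @return `read_height_map` returns the height-map matrix (1-based slice
#'   indices).
#' @export
read_height_map <- function(path) {
  if (!file.exists(path)) stop("cannot read height-map: no such file: ", path)
  p <- tiff::readTIFF(path)
  if (!is.matrix(p)) p <- p[, , 1L]
  p + 1
}

#' Read a label mask (TIFF or PNG)
#'
#' TIFF masks are read as stored. PNG masks are rescaled back to integer
#' labels using the file bit depth. Binary masks (values 0/1 only) are
#' converted to labels by 4-connected component labelling of the non-zero
#' regions, the zero band being the cell junctions.
#'
#' @param path mask file (.tif/.tiff/.png).
#' @return integer label matrix.
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) stop("cannot read mask: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth
    if (is.null(depth)) depth <- 8L
    if (!is.matrix(img)) img <- img[, , 1L]
    img <- round(img * (2^depth - 1))
    attributes(img) <- list(dim = dim(img))
    img
  } else {
    # as.is recovers raw integer labels from 8/16-bit files; float files
    # (e.g. written by write_label_mask) are already unscaled
    p <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) tiff::readTIFF(path))
    if (!is.matrix(p)) p <- p[, , 1L]
    round(p)
  }
  storage.mode(m) <- "integer"
  m
}

#' Write a label mask as a float TIFF
#' @param mask integer label matrix.
#' @param path output file.
#' @export
write_label_mask <- function(mask, path) {
  write_tiff_float(mask, path)
}
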