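# Independent brute-force reference implementations used across tests.
# Everything here is written with explicit loops and stays independent of
# the package internals it checks.

pad_sym_oracle <- function(m, r) {
  ny <- nrow(m); nx <- ncol(m)
  yi <- c(rev(seq_len(r)), seq_len(ny), ny - seq_len(r) + 1L)
  xi <- c(rev(seq_len(r)), seq_len(nx), nx - seq_len(r) + 1L)
  m[yi, xi, drop = FALSE]
}

window_oracle <- function(m, w, kind) {
  r <- (w - 1L) %/% 2L
  p <- pad_sym_oracle(m, r)
  out <- m
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    v <- p[i:(i + w - 1L), j:(j + w - 1L)]
    out[i, j] <- switch(kind,
      mean = mean(v),
      std = sqrt(mean((v - mean(v))^2)),
      median = stats::median(v))
  }
  out
}

bin_oracle <- function(m, b) {
  nyo <- ceiling(nrow(m) / b); nxo <- ceiling(ncol(m) / b)
  out <- matrix(NA_real_, nyo, nxo)
  for (i in seq_len(nyo)) for (j in seq_len(nxo)) {
    rows <- ((i - 1L) * b + 1L):min(nrow(m), i * b)
    cols <- ((j - 1L) * b + 1L):min(ncol(m), j * b)
    out[i, j] <- mean(m[rows, cols])
  }
  out
}

shoelace_oracle <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  s / 2
}

perimeter_oracle <- function(v) {
  n <- nrow(v)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + sqrt(sum((v[j, ] - v[i, ])^2))
  }
  s
}

rmse_oracle <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + (a[i, j] - b[i, j])^2
  sqrt(s / (nrow(a) * ncol(a)))
}

# Region adjacency within a Chebyshev reach, by quadruple loop.
adjacency_oracle <- function(mask, reach = 2L) {
  ny <- nrow(mask); nx <- ncol(mask)
  labs <- sort(unique(mask[mask > 0]))
  adj <- stats::setNames(lapply(labs, function(...) integer(0)),
                         as.character(labs))
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    a <- mask[i, j]
    if (a == 0) next
    for (di in (-reach):reach) for (dj in (-reach):reach) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > ny || jj < 1 || jj > nx) next
      b <- mask[ii, jj]
      if (b > 0 && b != a)
        adj[[as.character(a)]] <- union(adj[[as.character(a)]], b)
    }
  }
  lapply(adj, sort)
}

# Total-least-squares plane fit via SVD (independent of eigen-based path).
tls_plane_oracle <- function(v) {
  ctr <- colMeans(v)
  sv <- svd(sweep(v, 2L, ctr))
  n <- sv$v[, 3L]
  if (n[3] < 0) n <- -n
  n
}

# A deterministic simple star-shaped random polygon.
random_polygon <- function(n, r_min = 0.5, r_max = 1.5) {
  ang <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, r_min, r_max)
  cbind(x = r * cos(ang), y = r * sin(ang))
}
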