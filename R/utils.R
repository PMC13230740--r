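# Internal numeric helpers: truncated Gaussian kernels, boundary-renormalized
# separable convolution, box means. Shared by simkit, detection and focus.

# Truncated, normalized 1D Gaussian kernel. Radius 4*sigma (>= 1 tap).
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Dense n x n convolution matrix for kernel k with edge renormalization:
# each output row averages only the in-bounds taps, reweighted to sum to 1.
# A constant input therefore maps to the same constant exactly.
conv_matrix <- function(n, k) {
  r <- (length(k) - 1L) / 2L
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    w <- k[ok]
    M[i, j[ok]] <- w / sum(w)
  }
  M
}

# Separable convolution of a 3D array (z, y, x) with per-axis kernels.
# Implemented as three dense matrix products (fields are desk-scale).
sep_conv3d <- function(arr, kz, ky, kx) {
  d <- dim(arr)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (length(kz) > 1L) {
    arr <- array(conv_matrix(nz, kz) %*% matrix(arr, nz, ny * nx), dim = d)
  }
  if (length(ky) > 1L) {
    a <- aperm(arr, c(2, 1, 3))                       # (y, z, x)
    a <- array(conv_matrix(ny, ky) %*% matrix(a, ny, nz * nx),
               dim = c(ny, nz, nx))
    arr <- aperm(a, c(2, 1, 3))
  }
  if (length(kx) > 1L) {
    a <- aperm(arr, c(3, 1, 2))                       # (x, z, y)
    a <- array(conv_matrix(nx, kx) %*% matrix(a, nx, nz * ny),
               dim = c(nx, nz, ny))
    arr <- aperm(a, c(2, 3, 1))
  }
  arr
}

# 3D Gaussian smoothing with sigma = (axial, lateral) in (z, y/x).
gauss_smooth3d <- function(arr, sigma_lateral, sigma_axial) {
  sep_conv3d(arr, gauss_kernel(sigma_axial),
             gauss_kernel(sigma_lateral), gauss_kernel(sigma_lateral))
}

# 2D Gaussian blur of a matrix (y, x), boundary-renormalized.
gauss_blur2d <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  k <- gauss_kernel(sigma)
  conv_matrix(nrow(mat), k) %*% mat %*% t(conv_matrix(ncol(mat), k))
}

# Local mean over a window_px x window_px box, edge-truncated (the mean is
# taken over the in-bounds part of the window). Uses summed-area tables.
box_mean2d <- function(mat, window_px) {
  r <- (window_px - 1L) / 2L
  ny <- nrow(mat); nx <- ncol(mat)
  S <- matrix(0, ny + 1L, nx + 1L)
  S[-1L, -1L] <- apply(apply(mat, 2, cumsum), 1, cumsum) |> t()
  y0 <- pmax(0L, seq_len(ny) - r - 1L); y1 <- pmin(ny, seq_len(ny) + r)
  x0 <- pmax(0L, seq_len(nx) - r - 1L); x1 <- pmin(nx, seq_len(nx) + r)
  tot <- S[y1 + 1L, x1 + 1L, drop = FALSE] - S[y0 + 1L, x1 + 1L, drop = FALSE] -
    S[y1 + 1L, x0 + 1L, drop = FALSE] + S[y0 + 1L, x0 + 1L, drop = FALSE]
  cnt <- outer(y1 - y0, x1 - x0)
  tot / cnt
}

# Parabolic 3-point subpixel refinement: offset of the vertex of the
# parabola through (-1, ym), (0, y0), (1, yp), clamped to [-0.5, 0.5].
parabolic_offset <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (!is.finite(den) || den >= 0) return(0)   # not a local max / flat
  max(-0.5, min(0.5, 0.5 * (ym - yp) / den))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
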