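# registration: per-round global drift estimation by phase
# cross-correlation on binary spot maps or maximum-intensity projections,
# with optional subpixel refinement by local upsampled DFT evaluation.

#' Rasterize a spot table into a 2D binary map
#'
#' A disk of `dot_radius_px` is set at each spot's rounded `(y, x)`
#' position; z is collapsed. Spots falling outside the map are dropped.
#'
#' @param spots Spot table (needs columns `y`, `x`).
#' @param shape `(ny, nx)` of the output map.
#' @param dot_radius_px Disk radius in pixels (0 = single pixel).
#' @return A `(ny, nx)` matrix of 0/1.
#' @export
spots_to_binary_map <- function(spots, shape, dot_radius_px = 2) {
  ny <- shape[1]; nx <- shape[2]
  map <- matrix(0, ny, nx)
  if (nrow(spots) == 0L) return(map)
  yi <- round(spots$y); xi <- round(spots$x)
  ok <- yi >= 0 & yi <= ny - 1 & xi >= 0 & xi <= nx - 1
  yi <- yi[ok]; xi <- xi[ok]
  r <- dot_radius_px
  ri <- floor(r)
  offs <- expand.grid(dy = -ri:ri, dx = -ri:ri)
  offs <- offs[offs$dy^2 + offs$dx^2 <= r^2, , drop = FALSE]
  for (k in seq_len(nrow(offs))) {
    y <- yi + offs$dy[k]; x <- xi + offs$dx[k]
    keep <- y >= 0 & y <= ny - 1 & x >= 0 & x <= nx - 1
    map[cbind(y[keep] + 1, x[keep] + 1)] <- 1
  }
  map
}

# centered DFT frequency indices 0, 1, ..., n/2-1, -n/2, ..., -1
fft_freq_idx <- function(n) {
  ((seq_len(n) - 1L + floor(n / 2)) %% n) - floor(n / 2)
}

#' Global translation between two images by phase cross-correlation
#'
#' Computes the normalized cross-power spectrum of the two images; the peak
#' of its inverse transform gives the integer translation, optionally
#' refined to subpixel precision by evaluating the upsampled DFT in a
#' 1.5 px neighborhood of the peak (matrix-multiply DFT). Sign convention:
#' adding the returned `(delta_y, delta_x)` to coordinates measured in
#' `moving` lands them in the frame of `reference`.
#'
#' @param reference,moving 2D matrices of identical shape, non-constant.
#' @param upsample Upsampling factor (integer >= 1; 1 = integer shift).
#' @return List with `delta_y`, `delta_x` and `peak_ratio` (correlation
#'   peak over the strongest secondary peak; >= 1, higher = more reliable).
#' @export
phase_correlation_shift <- function(reference, moving, upsample = 20L) {
  stopifnot(is.matrix(reference), is.matrix(moving),
            all(dim(reference) == dim(moving)), upsample >= 1)
  if (sd(reference) == 0 || sd(moving) == 0)
    stop("constant image: phase correlation undefined")
  ny <- nrow(reference); nx <- ncol(reference)
  P <- fft(reference) * Conj(fft(moving))
  mag <- Mod(P)
  R <- P
  nzv <- mag > max(mag) * 1e-12
  R[nzv] <- P[nzv] / mag[nzv]
  R[!nzv] <- 0
  cc <- Re(fft(R, inverse = TRUE)) / (ny * nx)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # secondary peak outside a 5x5 wraparound exclusion zone
  ey <- ((pk[1] - 1 + (-2:2)) %% ny) + 1
  ex <- ((pk[2] - 1 + (-2:2)) %% nx) + 1
  cc2 <- cc; cc2[ey, ex] <- -Inf
  second <- max(cc2)
  peak_ratio <- max(cc) / max(second, max(cc) * 1e-6, 1e-12)
  peak_ratio <- max(1, peak_ratio)

  # the correlation peak sits at MINUS the content shift of `moving`
  # relative to `reference`, i.e. directly at the shift to add to moving
  # coordinates to reach the reference frame
  wrap <- function(p, n) ((p - 1 + floor(n / 2)) %% n) - floor(n / 2)
  sy <- wrap(pk[1], ny); sx <- wrap(pk[2], nx)

  if (upsample > 1) {
    span <- ceiling(1.5 * upsample)
    dftshift <- floor(span / 2)
    fy <- fft_freq_idx(ny); fx <- fft_freq_idx(nx)
    ky <- exp(2i * pi / (ny * upsample) *
                outer(sy * upsample + (seq_len(span) - 1 - dftshift), fy))
    kx <- exp(2i * pi / (nx * upsample) *
                outer(fx, sx * upsample + (seq_len(span) - 1 - dftshift)))
    cc_up <- Re(ky %*% R %*% kx)
    mx <- which(cc_up == max(cc_up), arr.ind = TRUE)[1, ]
    sy <- sy + (mx[1] - 1 - dftshift) / upsample
    sx <- sx + (mx[2] - 1 - dftshift) / upsample
  }
  list(delta_y = unname(as.numeric(sy)), delta_x = unname(as.numeric(sx)),
       peak_ratio = as.numeric(peak_ratio))
}

#' Estimate per-round drift against a reference round
#'
#' Registers every round to `reference_round` with phase cross-correlation,
#' either on binary spot maps (`mode = "spots"`) or on maximum-intensity
#' projections of the stacks (`mode = "image"`). A round with fewer than
#' `min_spots` spots in spots mode falls back to image mode when stacks are
#' available, else reports `(0, 0)` flagged `low_confidence`.
#'
#' @param spot_tables List of spot tables indexed by round (spots mode).
#' @param stacks List of [image_stack()]s indexed by round (image mode or
#'   fallback).
#' @param reference_round Reference round index.
#' @param mode `"spots"` or `"image"`.
#' @param shape `(ny, nx)` for binary maps (defaults to the stacks' shape).
#' @param dot_radius_px Disk radius for [spots_to_binary_map()].
#' @param upsample Subpixel upsampling factor.
#' @param min_spots Minimum spots for a usable binary map.
#' @return data.frame `(round, delta_y, delta_x, peak_ratio, mode, flags)`;
#'   deltas are the shifts to ADD to that round's coordinates to land in
#'   the reference frame, stored to 3 decimals.
#' @export
register_rounds <- function(spot_tables = NULL, stacks = NULL,
                            reference_round = 1L,
                            mode = c("spots", "image"), shape = NULL,
                            dot_radius_px = 2, upsample = 20L,
                            min_spots = 3L) {
  mode <- match.arg(mode)
  n_rounds <- if (mode == "spots") length(spot_tables) else length(stacks)
  if (reference_round < 1 || reference_round > n_rounds)
    stop("reference_round not present")
  if (mode == "image" && is.null(stacks)) stop("image mode needs stacks")
  if (mode == "spots" && is.null(spot_tables)) stop("spots mode needs spot tables")
  if (is.null(shape) && !is.null(stacks)) shape <- dim(stacks[[1]]$data)[2:3]
  if (mode == "spots" && is.null(shape))
    stop("spots mode needs `shape` (or stacks) for the binary maps")

  mip <- function(r) max_project(stacks[[r]])
  bmap <- function(r) spots_to_binary_map(spot_tables[[r]], shape, dot_radius_px)

  ref_img <- switch(mode, spots = bmap(reference_round),
                    image = mip(reference_round))
  out <- vector("list", n_rounds)
  for (r in seq_len(n_rounds)) {
    if (r == reference_round) {
      out[[r]] <- data.frame(round = r, delta_y = 0, delta_x = 0,
                             peak_ratio = Inf, mode = mode, flags = "",
                             stringsAsFactors = FALSE)
      next
    }
    used <- mode; flags <- ""
    if (mode == "spots" && nrow(spot_tables[[r]]) < min_spots) {
      if (!is.null(stacks)) {
        used <- "image"; flags <- "low_confidence;image_fallback"
      } else {
        out[[r]] <- data.frame(round = r, delta_y = 0, delta_x = 0,
                               peak_ratio = 1, mode = mode,
                               flags = "low_confidence", stringsAsFactors = FALSE)
        next
      }
    }
    mov <- switch(used, spots = bmap(r), image = mip(r))
    ref_used <- switch(used, spots = ref_img,
                       image = if (mode == "image") ref_img else mip(reference_round))
    est <- phase_correlation_shift(ref_used, mov, upsample = upsample)
    out[[r]] <- data.frame(round = r, delta_y = round(est$delta_y, 3),
                           delta_x = round(est$delta_x, 3),
                           peak_ratio = est$peak_ratio, mode = used,
                           flags = flags, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Apply a drift estimate to spot coordinates
#'
#' Adds `(delta_y, delta_x)` to the spot coordinates, moving them into the
#' reference frame. Out-of-bounds results are allowed (coordinates are a
#' frame of reference, not pixel indices).
#'
#' @param spots A spot table.
#' @param estimate A [register_rounds()] row (or any list with `delta_y`,
#'   `delta_x`).
#' @return The shifted spot table.
#' @export
apply_shift <- function(spots, estimate) {
  spots$y <- spots$y + estimate$delta_y
  spots$x <- spots$x + estimate$delta_x
  spots
}
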