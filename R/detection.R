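# detection: LoG filtering, local-maxima spot calling with subpixel
# refinement, and per-spot intensity / background / SNR metrics.

#' Detection parameters
#'
#' @param sigma_px PSF-matched filter sigma `(lateral, axial)` in px.
#' @param threshold Detection threshold on the (negated) LoG response, or
#'   `"auto"` for the elbow rule of [auto_threshold()].
#' @param min_separation_px Non-maximum-suppression radius (px, lateral).
#' @param signal_radius_px Radius around the peak treated as signal when
#'   measuring background; default `2 * sigma_lateral`.
#' @param background_annulus_px Inner/outer radii of the local-background
#'   annulus; default `c(3, 5) * sigma_lateral`. Inner must exceed
#'   `signal_radius_px`.
#' @return A `detection_params` object.
#' @export
detection_params <- function(sigma_px = c(1.5, 1.0), threshold = "auto",
                             min_separation_px = 3,
                             signal_radius_px = 2 * sigma_px[1],
                             background_annulus_px = c(3, 5) * sigma_px[1]) {
  stopifnot(all(sigma_px > 0), min_separation_px > 0, signal_radius_px > 0,
            length(background_annulus_px) == 2L)
  if (!identical(threshold, "auto") && (!is.numeric(threshold) || threshold <= 0))
    stop("threshold must be positive or \"auto\"")
  if (background_annulus_px[1] <= signal_radius_px)
    stop("annulus inner radius must exceed signal_radius_px")
  if (background_annulus_px[2] <= background_annulus_px[1])
    stop("annulus outer radius must exceed inner radius")
  structure(list(sigma_px = sigma_px, threshold = threshold,
                 min_separation_px = min_separation_px,
                 signal_radius_px = signal_radius_px,
                 background_annulus_px = background_annulus_px),
            class = "detection_params")
}

empty_spot_table <- function() {
  data.frame(round = integer(0), gene = character(0), z = numeric(0),
             y = numeric(0), x = numeric(0), intensity = numeric(0),
             background_mean = numeric(0), background_sd = numeric(0),
             snr = numeric(0), flags = character(0), stringsAsFactors = FALSE)
}

#' Laplacian-of-Gaussian filter (negated)
#'
#' Gaussian-smooths the stack (anisotropic: lateral sigma in y/x, axial in
#' z) and applies a negated discrete Laplacian scaled by `sigma_lateral^2`,
#' so diffraction-limited spots become positive peaks. Boundary kernels are
#' renormalized: a constant image maps to an all-zero response.
#'
#' @param stack An [image_stack()] (a matrix is promoted to one plane).
#' @param sigma_px Filter sigma `(lateral, axial)` in px.
#' @return An [image_stack()] holding the response (same shape).
#' @export
log_filter <- function(stack, sigma_px = c(1.5, 1.0)) {
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack)
  d <- dim(stack$data)
  if (any(sigma_px <= 0)) stop("sigma must be positive")
  if (sigma_px[1] > min(d[2], d[3]) / 2 ||
      (d[1] > 1 && sigma_px[2] > d[1] / 2))
    stop("sigma too large for the image extent")
  sm <- gauss_smooth3d(stack$data, sigma_px[1], sigma_px[2])
  lap <- array(0, dim = d)
  # replicate-padded discrete Laplacian per axis
  idx <- function(n, off) pmin(pmax(seq_len(n) + off, 1L), n)
  lap <- sm[idx(d[1], -1L), , , drop = FALSE] + sm[idx(d[1], 1L), , , drop = FALSE] +
    sm[, idx(d[2], -1L), , drop = FALSE] + sm[, idx(d[2], 1L), , drop = FALSE] +
    sm[, , idx(d[3], -1L), drop = FALSE] + sm[, , idx(d[3], 1L), drop = FALSE] -
    6 * sm
  out <- stack
  out$data <- -sigma_px[1]^2 * lap
  out
}

# 3D local maxima (26-connected, -Inf beyond the borders) of an array;
# returns an integer matrix of 0-based (z, y, x) voxel indices plus values.
local_maxima3d <- function(arr) {
  d <- dim(arr)
  shifted <- function(off) {
    # out[p] = arr[p + off], -Inf where p + off leaves the array
    out <- array(-Inf, dim = d)
    dst <- lapply(1:3, function(a) max(1L, 1L - off[a]):min(d[a], d[a] - off[a]))
    src <- lapply(1:3, function(a) dst[[a]] + off[a])
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  is_max <- array(TRUE, dim = d)
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz == 0 && dy == 0 && dx == 0) next
    nb <- shifted(c(dz, dy, dx))
    # strict on the "earlier" side to break plateau ties deterministically
    if (dz < 0 || (dz == 0 && (dy < 0 || (dy == 0 && dx < 0)))) {
      is_max <- is_max & (arr > nb)
    } else {
      is_max <- is_max & (arr >= nb)
    }
  }
  w <- which(is_max)
  if (length(w) == 0L)
    return(list(zyx = matrix(0L, 0, 3), value = numeric(0)))
  z <- (w - 1L) %% d[1]
  y <- ((w - 1L) %/% d[1]) %% d[2]
  x <- (w - 1L) %/% (d[1] * d[2])
  list(zyx = cbind(z = z, y = y, x = x), value = arr[w])
}

#' Automatic LoG threshold by the elbow rule
#'
#' Counts candidate local maxima above each threshold of a log-spaced grid
#' and picks the threshold whose point on the (threshold, count) curve lies
#' farthest below the chord between the curve's endpoints (axes normalized
#' to their range). On a field with real spots this lands at the start of
#' the plateau where the count stabilizes at the true-spot number. The rule
#' is linear: scaling the image scales the threshold.
#'
#' Degenerate inputs fall back to the 99.99th percentile of the candidate
#' maxima values, flagged: fewer than two candidates, a flat curve, or no
#' plateau (pure noise, recognized by the count collapsing between the
#' elbow and twice the elbow).
#'
#' @param filtered An [image_stack()] (or array) of LoG responses.
#' @param n_grid Grid size.
#' @return Threshold (numeric scalar) with attributes `method`
#'   (`"elbow"` or `"percentile_fallback"`) and `flag`.
#' @export
auto_threshold <- function(filtered, n_grid = 100L) {
  arr <- if (inherits(filtered, "image_stack")) filtered$data else filtered
  if (!all(is.finite(arr))) stop("filtered stack must be finite")
  lm <- local_maxima3d(arr)
  vals <- lm$value[lm$value > 0]
  fallback <- function() {
    th <- as.numeric(quantile(vals, 0.9999, names = FALSE))
    if (length(vals) == 0L) th <- Inf
    structure(th, method = "percentile_fallback", flag = "auto_fallback")
  }
  if (length(vals) < 2L) return(fallback())
  lo <- min(vals); hi <- max(vals)
  if (!(hi > lo)) return(fallback())
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  grid[1] <- lo; grid[n_grid] <- hi          # guard rounding of exp(log())
  counts <- vapply(grid, function(t) sum(vals >= t), numeric(1))
  if (length(unique(counts)) < 3L) return(fallback())
  # farthest below the chord, threshold axis normalized to its range and
  # count axis normalized on a log scale (the noise population dwarfs the
  # spot plateau in raw counts); the chord runs (0, 1) -> (1, 0), so the
  # distance below it is proportional to 1 - gx - gy
  gx <- (grid - lo) / (hi - lo)
  gy <- (log(counts) - log(min(counts))) / (log(max(counts)) - log(min(counts)))
  k <- which.max(1 - gx - gy)
  t_star <- grid[k]
  # plateau stability: with real spots the count barely changes between
  # t* and 2 t*; on pure noise it collapses, so fall back
  c1 <- counts[k]
  c2 <- sum(vals >= min(2 * t_star, hi))
  if (c1 < 2 || c2 < 0.6 * c1) return(fallback())
  # snap forward from the elbow to the low edge of the count plateau: keep
  # stepping while each grid step still sheds >= 1% of the candidates
  # (residual noise tail), within a bounded factor of the elbow
  while (k < n_grid && grid[k + 1] <= 2.5 * t_star &&
         (counts[k] - counts[k + 1]) >= 0.01 * max(counts[k + 1], 1))
    k <- k + 1L
  structure(grid[k], method = "elbow", flag = "")
}

#' Detect diffraction-limited spots in a stack
#'
#' LoG-filters the stack, selects 3D local maxima above threshold,
#' suppresses non-maxima within `min_separation_px` (keeping the stronger
#' response), refines each peak to subpixel precision by a 3-point
#' parabolic fit per axis, and fills intensity/background/SNR metrics via
#' [spot_metrics()].
#'
#' @param stack An [image_stack()].
#' @param params [detection_params()].
#' @param round,gene Labels stored in the output table.
#' @return A spot table: data.frame with columns `round, gene, z, y, x,
#'   intensity, background_mean, background_sd, snr, flags` (coordinates
#'   0-based px, subpixel).
#' @export
detect_spots <- function(stack, params = detection_params(),
                         round = 1L, gene = "gene") {
  stopifnot(inherits(params, "detection_params"))
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack)
  filt <- log_filter(stack, params$sigma_px)
  th <- params$threshold
  auto_flag <- ""
  if (identical(th, "auto")) {
    th <- auto_threshold(filt)
    if (attr(th, "method") == "percentile_fallback") auto_flag <- "auto_fallback"
    th <- as.numeric(th)
  }
  lm <- local_maxima3d(filt$data)
  keep <- lm$value >= th
  zyx <- lm$zyx[keep, , drop = FALSE]
  val <- lm$value[keep]
  if (nrow(zyx) == 0L) return(empty_spot_table())

  # greedy NMS by descending response, lateral distance
  ord <- order(-val)
  zyx <- zyx[ord, , drop = FALSE]; val <- val[ord]
  kept <- logical(length(val))
  for (i in seq_along(val)) {
    if (i == 1L) { kept[1L] <- TRUE; next }
    sel <- which(kept)
    d2 <- (zyx[sel, 2] - zyx[i, 2])^2 + (zyx[sel, 3] - zyx[i, 3])^2
    kept[i] <- all(d2 >= params$min_separation_px^2)
  }
  zyx <- zyx[kept, , drop = FALSE]; val <- val[kept]

  d <- dim(filt$data)
  sub <- matrix(0, nrow(zyx), 3)
  for (i in seq_len(nrow(zyx))) {
    p <- zyx[i, ] + 1L   # 1-based voxel
    for (ax in 1:3) {
      if (d[ax] < 3L) { sub[i, ax] <- zyx[i, ax]; next }
      pm <- p; pp <- p
      pm[ax] <- max(1L, p[ax] - 1L); pp[ax] <- min(d[ax], p[ax] + 1L)
      off <- parabolic_offset(filt$data[pm[1], pm[2], pm[3]],
                              filt$data[p[1], p[2], p[3]],
                              filt$data[pp[1], pp[2], pp[3]])
      sub[i, ax] <- zyx[i, ax] + off
    }
  }
  spots <- data.frame(round = as.integer(round), gene = gene,
                      z = sub[, 1], y = sub[, 2], x = sub[, 3],
                      intensity = NA_real_, background_mean = NA_real_,
                      background_sd = NA_real_, snr = NA_real_,
                      flags = auto_flag, stringsAsFactors = FALSE)
  spot_metrics(stack, spots, params)
}

#' Per-spot intensity, local background and SNR
#'
#' Background statistics come from an annulus
#' `background_annulus_px = (inner, outer)` around each spot in the spot's
#' central z-plane; `intensity = raw peak - background_mean` and
#' `snr = intensity / background_sd`. A spot whose annulus leaves the image
#' is flagged `annulus_clipped` and measured on the in-bounds portion. A
#' zero background SD yields `snr = Inf` and the flag `snr_infinite`.
#'
#' @param stack The raw [image_stack()] the spots were detected in.
#' @param spots A spot table (needs columns `z, y, x`).
#' @param params [detection_params()].
#' @return The spot table with metric columns filled.
#' @export
spot_metrics <- function(stack, spots, params = detection_params()) {
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack)
  d <- dim(stack$data)
  inner <- params$background_annulus_px[1]
  outer <- params$background_annulus_px[2]
  ro <- ceiling(outer)
  if (!"flags" %in% names(spots)) spots$flags <- ""
  for (i in seq_len(nrow(spots))) {
    zi <- min(max(round(spots$z[i]), 0), d[1] - 1)
    yi <- round(spots$y[i]); xi <- round(spots$x[i])
    plane <- stack$data[zi + 1, , ]
    yy <- max(0, yi - ro):min(d[2] - 1, yi + ro)
    xx <- max(0, xi - ro):min(d[3] - 1, xi + ro)
    clipped <- (yi - ro < 0) || (yi + ro > d[2] - 1) ||
      (xi - ro < 0) || (xi + ro > d[3] - 1)
    rr <- sqrt(outer((yy - spots$y[i])^2, (xx - spots$x[i])^2, "+"))
    ann <- plane[yy + 1, xx + 1, drop = FALSE][rr >= inner & rr <= outer]
    peak <- plane[min(max(yi, 0), d[2] - 1) + 1, min(max(xi, 0), d[3] - 1) + 1]
    bg_mean <- mean(ann)
    bg_sd <- if (length(ann) > 1L) sd(ann) else 0
    spots$background_mean[i] <- bg_mean
    spots$background_sd[i] <- bg_sd
    spots$intensity[i] <- peak - bg_mean
    fl <- spots$flags[i]
    if (clipped) fl <- paste_flag(fl, "annulus_clipped")
    if (bg_sd > 0) {
      spots$snr[i] <- spots$intensity[i] / bg_sd
    } else {
      spots$snr[i] <- Inf
      fl <- paste_flag(fl, "snr_infinite")
    }
    spots$flags[i] <- fl
  }
  spots
}

paste_flag <- function(flags, new) {
  ifelse(new == "", flags,
         ifelse(flags == "", new, paste(flags, new, sep = ";")))
}

#' Per-round summary of spot tables
#'
#' One row per (gene, round): spot count plus median and interquartile
#' range of intensity, background and SNR — the round-wise QC trends used
#' to judge detection stability across hybridization cycles.
#'
#' @param spots A spot table or list of spot tables (rbind-ed).
#' @return A data.frame with columns `gene, round, n_spots,
#'   median_intensity, iqr_lo_intensity, iqr_hi_intensity,
#'   median_background, ..., median_snr, ..., flags`.
#' @export
round_summary <- function(spots) {
  if (is.list(spots) && !is.data.frame(spots)) spots <- do.call(rbind, spots)
  if (nrow(spots) == 0L) stop("round_summary needs at least one round")
  key <- interaction(spots$gene, spots$round, drop = TRUE)
  rows <- lapply(split(spots, key), function(s) {
    q <- function(v, p) if (nrow(s) > 0) as.numeric(quantile(v, p, na.rm = TRUE)) else NA_real_
    data.frame(gene = s$gene[1], round = s$round[1], n_spots = nrow(s),
               median_intensity = q(s$intensity, 0.5),
               iqr_lo_intensity = q(s$intensity, 0.25),
               iqr_hi_intensity = q(s$intensity, 0.75),
               median_background = q(s$background_mean, 0.5),
               iqr_lo_background = q(s$background_mean, 0.25),
               iqr_hi_background = q(s$background_mean, 0.75),
               median_snr = q(s$snr[is.finite(s$snr)], 0.5),
               iqr_lo_snr = q(s$snr[is.finite(s$snr)], 0.25),
               iqr_hi_snr = q(s$snr[is.finite(s$snr)], 0.75),
               flags = if (nrow(s) == 0) "empty_round" else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$round), ]
  rownames(out) <- NULL
  out
}
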