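# focus: shape-from-focus scoring of nuclear stacks with the
# Helmli-Scherer mean-ratio contrast, per-nucleus best-plane selection and
# best-focus composite images.

#' Helmli-Scherer mean-ratio contrast map
#'
#' For each pixel, with `mu` the local mean over a `window_px` square
#' (edge-truncated), the contrast is `R = max(I/mu, mu/I)`; `R = 1` where
#' both `I` and `mu` are zero. The measure is >= 1 everywhere, equals 1
#' exactly on constant images, is invariant to multiplying the image by a
#' positive constant, and decreases as the image is blurred — the sharpest
#' plane of a textured object scores highest.
#'
#' @param plane 2D numeric matrix (non-negative intensities).
#' @param window_px Odd window size >= 3.
#' @param cap Cap applied where `mu = 0` with `I > 0` (or vice versa);
#'   such pixels are otherwise unbounded.
#' @return Matrix of contrast values, same shape; attribute `capped` gives
#'   the number of capped pixels.
#' @export
mean_ratio_contrast <- function(plane, window_px = 7L, cap = 1e6) {
  stopifnot(is.matrix(plane))
  if (window_px < 3L || window_px %% 2L == 0L)
    stop("window_px must be odd and >= 3")
  mu <- box_mean2d(plane, window_px)
  both_zero <- plane == 0 & mu == 0
  r1 <- ifelse(mu > 0, plane / mu, cap)
  r2 <- ifelse(plane > 0, mu / plane, cap)
  R <- pmax(r1, r2)
  R[both_zero] <- 1
  R <- pmin(R, cap)
  structure(R, capped = sum(R == cap))
}

#' Per-nucleus focus curves and best focal plane
#'
#' Computes the mean-ratio contrast of every z-plane and, for each labeled
#' nucleus, averages it over the nucleus's bounding box per plane. The
#' best plane is the argmax of this focus curve (ties resolved to the
#' lowest z).
#'
#' @param stack An [image_stack()] (e.g. a DAPI stack).
#' @param label_mask 2D integer matrix `(ny, nx)`; 0 = background, labels
#'   >= 1 mark nuclei.
#' @param window_px Contrast window (see [mean_ratio_contrast()]).
#' @param use_mask Restrict scoring to mask pixels instead of the full
#'   bounding box (default FALSE: bounding box).
#' @return A `focus_result`: list with `per_nucleus` (data.frame `label,
#'   y0, x0, y1, x1, best_z, fm_best` — bbox half-open, 0-based) and
#'   `curves` (matrix nuclei x nz of mean contrast).
#' @export
nucleus_focus_curves <- function(stack, label_mask, window_px = 7L,
                                 use_mask = FALSE) {
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack)
  d <- dim(stack$data)
  stopifnot(all(dim(label_mask) == d[2:3]))
  labels <- sort(unique(label_mask[label_mask > 0]))
  if (length(labels) == 0L)
    return(structure(list(per_nucleus = data.frame(
      label = integer(0), y0 = integer(0), x0 = integer(0), y1 = integer(0),
      x1 = integer(0), best_z = integer(0), fm_best = numeric(0)),
      curves = matrix(0, 0, d[1]), window_px = window_px),
      class = "focus_result"))
  cmaps <- lapply(seq_len(d[1]), function(z)
    mean_ratio_contrast(stack$data[z, , ], window_px))
  per <- vector("list", length(labels))
  curves <- matrix(NA_real_, length(labels), d[1])
  for (i in seq_along(labels)) {
    sel <- which(label_mask == labels[i], arr.ind = TRUE)
    y0 <- min(sel[, 1]) - 1L; y1 <- max(sel[, 1])      # half-open, 0-based
    x0 <- min(sel[, 2]) - 1L; x1 <- max(sel[, 2])
    for (z in seq_len(d[1])) {
      curves[i, z] <- if (use_mask) mean(cmaps[[z]][sel])
      else mean(cmaps[[z]][(y0 + 1):y1, (x0 + 1):x1])
    }
    bz <- which.max(curves[i, ]) - 1L                  # ties -> lowest z
    per[[i]] <- data.frame(label = labels[i], y0 = y0, x0 = x0, y1 = y1,
                           x1 = x1, best_z = bz,
                           fm_best = curves[i, bz + 1L])
  }
  structure(list(per_nucleus = do.call(rbind, per), curves = curves,
                 window_px = window_px),
            class = "focus_result")
}

#' Best-focus composite image
#'
#' Pixels of each nucleus are taken from that nucleus's best focal plane;
#' background pixels come from the plane at the median of the per-nucleus
#' best-z values (median rounded to nearest integer, ties to the lower z).
#' With no nuclei the middle plane is returned, flagged.
#'
#' @param stack An [image_stack()].
#' @param label_mask 2D integer label mask.
#' @param focus_results A `focus_result` covering all labels in the mask.
#' @return 2D matrix; attribute `background_z` gives the fill plane and
#'   `flag` is non-empty when no nuclei were present.
#' @export
composite_best_focus <- function(stack, label_mask, focus_results) {
  if (!inherits(stack, "image_stack")) stack <- image_stack(stack)
  d <- dim(stack$data)
  per <- focus_results$per_nucleus
  labels <- sort(unique(label_mask[label_mask > 0]))
  if (!all(labels %in% per$label))
    stop("focus_results must cover all labels in the mask")
  if (length(labels) == 0L) {
    mid <- floor((d[1] - 1) / 2)
    return(structure(stack$data[mid + 1, , ], background_z = mid,
                     flag = "no_nuclei"))
  }
  med <- median(per$best_z)
  bg_z <- if (med %% 1 == 0.5) floor(med) else round(med)   # ties -> lower
  out <- stack$data[bg_z + 1, , ]
  for (i in seq_len(nrow(per))) {
    sel <- label_mask == per$label[i]
    plane <- stack$data[per$best_z[i] + 1, , ]
    out[sel] <- plane[sel]
  }
  structure(out, background_z = bg_z, flag = "")
}

#' Threshold-based nucleus segmentation (fallback)
#'
#' A simple segmenter for tests and demos: Otsu global threshold on the
#' projection, hole filling, connected components, and a minimum-size
#' filter. External label masks (e.g. from a learned segmenter) are
#' accepted everywhere a mask is consumed; this fallback makes the package
#' self-contained.
#'
#' @param projection 2D matrix (e.g. [max_project()] of a DAPI stack).
#' @param min_size_px Minimum object area in pixels.
#' @return Integer label mask (0 background; labels are consecutive
#'   positive integers); attribute `flag` is `"empty_mask"` when nothing
#'   was found.
#' @export
segment_nuclei_fallback <- function(projection, min_size_px = 50L) {
  stopifnot(is.matrix(projection))
  rng <- range(projection)
  if (rng[1] == rng[2])
    return(structure(matrix(0L, nrow(projection), ncol(projection)),
                     flag = "empty_mask"))
  norm <- (projection - rng[1]) / (rng[2] - rng[1])
  # EBImage images are (x, y); transpose in and out
  img <- EBImage::Image(t(norm))
  th <- EBImage::otsu(img, range = c(0, 1))
  bin <- EBImage::fillHull(img > th)
  lab <- EBImage::bwlabel(bin)
  m <- t(EBImage::imageData(lab))
  sizes <- table(m[m > 0])
  keep <- as.integer(names(sizes)[sizes >= min_size_px])
  m[!(m %in% keep)] <- 0L
  relab <- match(m, sort(unique(m[m > 0])))          # consecutive 1..K
  out <- matrix(ifelse(is.na(relab), 0L, relab), nrow(m), ncol(m))
  structure(out, flag = if (max(out) == 0L) "empty_mask" else "")
}

#' Summarize best-plane focus measures per condition
#'
#' Boxplot-ready statistics of `fm_best` across the nuclei of each
#' condition (e.g. different sample-preparation protocols).
#'
#' @param results Named list of `focus_result` objects, one per condition.
#' @return data.frame `(condition, n, median, q25, q75)`.
#' @export
condition_summary <- function(results) {
  stopifnot(length(results) >= 1L)
  if (is.null(names(results)))
    names(results) <- paste0("condition", seq_along(results))
  rows <- lapply(names(results), function(cn) {
    fm <- results[[cn]]$per_nucleus$fm_best
    data.frame(condition = cn, n = length(fm),
               median = median(fm), q25 = as.numeric(quantile(fm, 0.25)),
               q75 = as.numeric(quantile(fm, 0.75)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
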