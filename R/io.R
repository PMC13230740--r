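#' Create an image stack
#'
#' The unit of acquisition: one 3D intensity array per field of view, round
#' and channel, indexed `(z, y, x)` with 0-based coordinate conventions
#' throughout the package.
#'
#' @param data 3D numeric array `(z, y, x)` of finite, non-negative
#'   intensities. A 2D matrix is promoted to a single-plane stack.
#' @param pixel_size_nm Lateral pixel size in nanometres.
#' @param z_step_nm Axial plane spacing in nanometres.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, pixel_size_nm = 100, z_step_nm = 300) {
  if (is.matrix(data)) data <- array(data, dim = c(1L, dim(data)))
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!all(is.finite(data))) stop("image data must be finite")
  if (pixel_size_nm <= 0 || z_step_nm <= 0) stop("spacings must be positive")
  structure(list(data = data, pixel_size_nm = pixel_size_nm,
                 z_step_nm = z_step_nm),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d z-planes x %d x %d px, %.0f nm/px, %.0f nm z-step\n",
              d[1], d[2], d[3], x$pixel_size_nm, x$z_step_nm))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' Maximum intensity projection of a stack along z
#'
#' @param stack An [image_stack()].
#' @return A `(ny, nx)` matrix.
#' @export
max_project <- function(stack) {
  apply(stack$data, c(2, 3), max)
}

#' Read / write image stacks as multi-page TIFF
#'
#' Stacks are stored one z-plane per TIFF page as 32-bit floats scaled by
#' 1/65536 (camera counts up to 16 bit round-trip losslessly within float
#' precision). Pixel metadata is not stored in the TIFF and must be
#' supplied on read.
#'
#' @param stack An [image_stack()].
#' @param path File path ending in `.tif`.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns an [image_stack()].
#' @export
write_stack_tiff <- function(stack, path) {
  planes <- lapply(seq_len(dim(stack$data)[1]),
                   function(z) stack$data[z, , ] / 65536)
  if (max(stack$data) > 65536)
    warning("intensities above 65536 are clipped in the TIFF")
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @param pixel_size_nm,z_step_nm Spacing metadata to attach on read.
#' @export
read_stack_tiff <- function(path, pixel_size_nm = 100, z_step_nm = 300) {
  planes <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(planes)) planes <- list(planes)
  arr <- array(0, dim = c(length(planes), nrow(planes[[1]]), ncol(planes[[1]])))
  for (z in seq_along(planes)) arr[z, , ] <- planes[[z]] * 65536
  image_stack(arr, pixel_size_nm, z_step_nm)
}

# Canonical round/channel TIFF filename, e.g. r03_chXPO1.tif
round_tiff_name <- function(round, channel) {
  sprintf("r%02d_ch%s.tif", round, channel)
}

# CSV conventions: RFC-4180, UTF-8, '.' decimal, no row names.
write_table_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
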