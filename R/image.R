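#' Calibrated 8-bit intensity image
#'
#' Container for a single-channel fluorescence image: an integer intensity
#' grid on the 256-level scale (0--255) together with the physical pixel
#' size. Every length reported by the pipeline is converted through
#' `pixel_size`; images without a known calibration cannot be measured.
#'
#' @param grid Integer matrix of intensities in `[0, 255]`; rows run top to
#'   bottom, columns left to right.
#' @param pixel_size Physical size of one pixel in micrometres (> 0).
#' @return An object of class `calibrated_image`.
#' @examples
#' img <- calibrated_image(matrix(0L, 56, 76), pixel_size = 0.5)
#' dim(img$grid)
#' @export
calibrated_image <- function(grid, pixel_size) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix")
  if (anyNA(grid)) stop("`grid` must not contain NA")
  if (any(grid < 0) || any(grid > 255))
    stop("intensities must lie in [0, 255]")
  if (any(grid != round(grid)))
    stop("intensities must be integers on the 0-255 scale")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (um/pixel)")
  storage.mode(grid) <- "integer"
  structure(list(grid = grid, pixel_size = pixel_size),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.3g um/px, intensity [%d, %d]\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size,
              min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
dim.calibrated_image <- function(x) dim(x$grid)

#' @rdname calibrated_image
#' @param x A `calibrated_image`.
#' @param ... Further arguments passed to [graphics::image()].
#' @export
plot.calibrated_image <- function(x, ...) {
  g <- x$grid
  # transpose + flip so that the display matches the stored row/col layout
  graphics::image(x = seq_len(ncol(g)), y = seq_len(nrow(g)),
                  z = t(g[nrow(g):1, , drop = FALSE]),
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  zlim = c(0, 255), asp = 1, xlab = "col (px)",
                  ylab = "row (px)", useRaster = TRUE, ...)
  invisible(x)
}

as_calibrated_image <- function(x, pixel_size) {
  if (inherits(x, "calibrated_image")) return(x)
  calibrated_image(x, pixel_size)
}
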