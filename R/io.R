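#' Read an 8-bit grayscale image with physical calibration
#'
#' Reads TIFF or PNG (lossless, round-trip exact) or JPEG (read-only, with
#' a warning about compression artifacts). Multi-channel images are
#' collapsed to grayscale by the Rec. 601 luminance weights. The physical
#' pixel size must always be supplied: stored image files carry no
#' trustworthy calibration and micrometre-scale measurements are
#' meaningless without one.
#'
#' @param path Path to the image file.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @return A [calibrated_image()].
#' @export
read_image <- function(path, pixel_size) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = {
      out <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                      error = function(e)
                        stop(sprintf("format error reading %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
      out
    },
    png = {
      out <- tryCatch(png::readPNG(path),
                      error = function(e)
                        stop(sprintf("format error reading %s: %s", path,
                                     conditionMessage(e)), call. = FALSE))
      round(out * 255)
    },
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("JPEG support requires the 'jpeg' package")
      warning(sprintf(
        "%s: JPEG is lossy; measurements may carry compression artifacts",
        basename(path)))
      round(jpeg::readJPEG(path) * 255)
    },
    stop(sprintf("format error: unsupported image format '.%s' (%s)",
                 ext, path))
  )
  if (length(dim(arr)) == 3L) {
    w <- c(0.299, 0.587, 0.114)[seq_len(dim(arr)[3])]
    arr <- round(apply(sweep(arr, 3, w / sum(w), `*`), c(1, 2), sum))
  }
  calibrated_image(clip255(arr), pixel_size)
}

#' Write an image as 8-bit grayscale TIFF or PNG
#'
#' Lossless: `read_image(write_image(x))` reproduces the intensity grid
#' bit-exactly for both formats.
#'
#' @param image A [calibrated_image()].
#' @param path Destination path; format from the extension (.tif/.tiff or
#'   .png).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (!inherits(image, "calibrated_image"))
    stop("`image` must be a calibrated_image")
  ext <- tolower(tools::file_ext(path))
  g <- image$grid / 255
  switch(ext,
    tif = , tiff = tiff::writeTIFF(g, path, bits.per.sample = 8L,
                                   compression = "none"),
    png = png::writePNG(g, path),
    stop(sprintf("format error: unsupported output format '.%s'", ext)))
  invisible(path)
}

#' Write / read a frame sequence as multi-page TIFF
#'
#' @param frames List of [calibrated_image()] frames with equal dims and
#'   pixel size.
#' @param path Destination `.tif` path. A JSON sidecar `<path>.json`
#'   records the pixel size and frame times so the sequence is
#'   self-describing.
#' @param times_h Frame times in hours (stored in the sidecar).
#' @return `path`, invisibly.
#' @export
write_sequence <- function(frames, path, times_h = NULL) {
  if (!length(frames)) stop("empty frame list")
  ps <- frames[[1]]$pixel_size
  tiff::writeTIFF(lapply(frames, function(f) f$grid / 255), path,
                  bits.per.sample = 8L, compression = "none")
  meta <- list(pixel_size_um = ps,
               n_frames = length(frames),
               times_h = times_h)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_sequence
#' @param pixel_size Pixel size in um/px; defaults to the sidecar value
#'   when present.
#' @return `read_sequence`: a list with `frames` (list of
#'   [calibrated_image()]) and `times_h`.
#' @export
read_sequence <- function(path, pixel_size = NULL) {
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  ps <- pixel_size %||% meta$pixel_size_um
  if (is.null(ps)) stop("pixel_size is required (no sidecar found)")
  pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  list(frames = lapply(pages, calibrated_image, pixel_size = ps),
       times_h = if (!is.null(meta$times_h)) unlist(meta$times_h) else NULL)
}

#' Pipeline configuration
#'
#' Validated bundle of every tunable the end-to-end pipeline uses. The
#' physical calibration is mandatory and never inferred from image files.
#'
#' @param pixel_size Pixel size in micrometres per pixel (> 0).
#' @param threshold Threshold method id; only `"otsu"` is available.
#' @param min_size_factor Fraction of the smallest reference-cell area
#'   used as the minimum object size (see [calibrate_min_size()]).
#' @param gate_um Tracking gate in micrometres per sampling step.
#' @param interval_h Tracking sampling interval in hours.
#' @param seed Integer seed threaded to all stochastic stages.
#' @param output_dir Directory for pipeline outputs.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(pixel_size, threshold = "otsu",
                            min_size_factor = 0.5, gate_um = 100,
                            interval_h = 12, seed = 1L,
                            output_dir = tempfile("fibromorph-run-")) {
  if (missing(pixel_size) || !is.numeric(pixel_size) || pixel_size <= 0)
    stop("config validation error: `pixel_size` (um/px) is mandatory and must be > 0")
  threshold <- match.arg(threshold, "otsu")
  if (min_size_factor <= 0)
    stop("config validation error: `min_size_factor` must be > 0")
  if (gate_um <= 0) stop("config validation error: `gate_um` must be > 0")
  if (interval_h <= 0) stop("config validation error: `interval_h` must be > 0")
  structure(list(pixel_size = pixel_size, threshold = threshold,
                 min_size_factor = min_size_factor, gate_um = gate_um,
                 interval_h = interval_h, seed = as.integer(seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path Destination YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}
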