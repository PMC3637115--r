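#' Automated intensity threshold (Otsu)
#'
#' Chooses a global threshold on the 0--255 intensity histogram by
#' maximizing the between-class variance (Otsu's criterion), removing the
#' influence of illumination differences and operator settings. Pixels
#' strictly above the returned level are foreground; pixels at or below it
#' are cut off as background.
#'
#' @param image A [calibrated_image()] (or plain integer matrix in 0--255).
#' @param min_separation Minimum contrast, in pooled within-class standard
#'   deviations, between the two class means for the image to count as
#'   containing signal (default 4). Fluorescent objects sit tens of noise
#'   SDs above background; an image of pure background noise still has an
#'   Otsu split, but its class means sit only ~2--3 within-class SDs apart
#'   and thresholding it would turn noise into spurious percolating
#'   objects. Such images yield `signal = FALSE` and an empty mask.
#' @return A list with `level` (the chosen threshold, an integer in
#'   0--254), `mask` (logical matrix of foreground pixels, `grid > level`;
#'   all-`FALSE` when no signal was found) and `signal` (logical).
#' @details Ties in the between-class variance are broken towards the lowest
#'   level, making the result deterministic. A constant image has no
#'   two-class structure and raises an error.
#' @examples
#' g <- matrix(10L, 40, 40); g[10:20, 10:20] <- 200L
#' auto_threshold(calibrated_image(g, 0.5))$level
#' @export
auto_threshold <- function(image, min_separation = 4) {
  g <- if (inherits(image, "calibrated_image")) image$grid else image
  if (length(g) == 0L) stop("image is empty")
  counts <- as.numeric(tabulate(as.vector(g) + 1L, nbins = 256L))
  if (sum(counts > 0) < 2L)
    stop("degenerate histogram: image has a single intensity value")
  n <- sum(counts)
  lev <- 0:255
  w0 <- cumsum(counts)                # pixels at intensity <= t
  m0 <- cumsum(counts * lev)          # intensity-weighted cumulative sum
  mt <- m0[256L]
  w1 <- n - w0
  sigma_b <- rep(-Inf, 255L)          # candidate thresholds t = 0..254
  valid <- w0[1:255] > 0L & w1[1:255] > 0L
  mu0 <- m0[1:255] / w0[1:255]
  mu1 <- (mt - m0[1:255]) / w1[1:255]
  sigma_b[valid] <- (w0[1:255] * w1[1:255])[valid] *
    (mu0[valid] - mu1[valid])^2
  level <- which.max(sigma_b) - 1L    # first maximum -> lowest level
  v <- as.numeric(g)
  lo <- v[v <= level]; hi <- v[v > level]
  pooled_sd <- sqrt((sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) / n)
  signal <- pooled_sd == 0 ||
    (mean(hi) - mean(lo)) >= min_separation * pooled_sd
  mask <- if (signal) g > level else
    matrix(FALSE, nrow(g), ncol(g))
  list(level = level, mask = mask, signal = signal)
}

#' Minimum object size from reference measurements
#'
#' The minimum pixel area for an object to enter the count is calibrated
#' from the measured areas of representative cells (canonically twelve):
#' `min_size = floor(factor * min(reference_areas))`, with `factor = 0.5`
#' by default so that every reference cell clears the gate with margin.
#'
#' @param reference_areas Numeric vector of measured cell areas in pixels
#'   (all > 0; canonically 12 entries).
#' @param factor Fraction of the smallest reference area to use (default 0.5).
#' @return Minimum object size in pixels (integer).
#' @examples
#' calibrate_min_size(c(900, 1200, 1500))
#' @export
calibrate_min_size <- function(reference_areas, factor = 0.5) {
  if (length(reference_areas) == 0L)
    stop("`reference_areas` must be a nonempty vector of pixel areas")
  if (any(!is.finite(reference_areas)) || any(reference_areas <= 0))
    stop("all reference areas must be positive")
  if (factor <= 0) stop("`factor` must be positive")
  as.integer(floor(factor * min(reference_areas)))
}

# 8-connected component labeling: EBImage::bwlabel (4-connected) followed by
# union-find merging of diagonally adjacent labels, then relabeling in
# raster-scan (row-major, top-left origin) order of first appearance.
label_components <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(m)
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  nlab <- max(lab)
  if (nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]    # diagonal \
    a2 <- lab[-1, -nc]; b2 <- lab[-nr, -1]    # diagonal /
    sel1 <- a1 > 0L & b1 > 0L & a1 != b1
    sel2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]),
                          cbind(a2[sel2], b2[sel2])))
    if (nrow(pairs) > 0L) {
      parent <- seq_len(nlab)
      find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
      for (k in seq_len(nrow(pairs))) {
        r1 <- find(pairs[k, 1]); r2 <- find(pairs[k, 2])
        if (r1 != r2) parent[max(r1, r2)] <- min(r1, r2)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      lab[lab > 0L] <- root[lab[lab > 0L]]
    }
  }
  # relabel by raster-scan order of first pixel
  pos <- which(lab > 0L)
  if (length(pos) == 0L) return(lab)
  nr <- nrow(lab)
  r <- ((pos - 1L) %% nr); c <- ((pos - 1L) %/% nr)
  raster <- r * ncol(lab) + c
  labs <- lab[pos]
  firsts <- tapply(raster, labs, min)
  ord <- rank(firsts, ties.method = "first")
  newlab <- integer(max(labs))
  newlab[as.integer(names(firsts))] <- as.integer(ord)
  lab[pos] <- newlab[labs]
  lab
}

#' Detect discrete objects (ROIs) in a binary mask
#'
#' Draws a region of interest around each discrete fluorescent object:
#' 8-connected components of the thresholded mask with at least `min_size`
#' pixels, labeled in deterministic raster-scan order. Each object carries
#' its pixel set, bounding box and a sub-pixel boundary polygon (the
#' marching-squares iso-contour of the component at level 0.5).
#'
#' @param mask Logical or 0/1 matrix (typically from [auto_threshold()]).
#' @param min_size Minimum pixel count for an object to be kept (>= 1);
#'   see [calibrate_min_size()].
#' @return A list of `roi_object`s, each with `label`, `pixels` (n x 2
#'   matrix of 0-based (row, col) indices), `boundary` (outer contour,
#'   0-based (row, col) coordinates), `bbox` `(row0, col0, row1, col1)` and
#'   `area_px`. An empty list when nothing passes the gate.
#' @examples
#' g <- matrix(10L, 40, 40); g[5:15, 5:15] <- 200L
#' th <- auto_threshold(calibrated_image(g, 0.5))
#' length(detect_objects(th$mask, min_size = 10))
#' @export
detect_objects <- function(mask, min_size = 1L) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  if (min_size < 1L) stop("`min_size` must be >= 1")
  lab <- label_components(mask != 0)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  out <- list()
  nr <- nrow(lab)
  for (lb in seq_len(nlab)) {
    pos <- which(lab == lb)
    if (length(pos) < min_size) next
    r1 <- ((pos - 1L) %% nr) + 1L
    c1 <- ((pos - 1L) %/% nr) + 1L
    bbox <- c(min(r1), min(c1), max(r1), max(c1)) - 1L
    sub <- matrix(0L, bbox[3] - bbox[1] + 1L, bbox[4] - bbox[2] + 1L)
    sub[cbind(r1 - bbox[1], c1 - bbox[2])] <- 1L
    loops <- ms_contours(sub)
    areas <- vapply(loops, function(P) abs(poly_area_signed(P)), numeric(1))
    outer <- loops[[which.max(areas)]]
    outer[, 1] <- outer[, 1] + bbox[1]
    outer[, 2] <- outer[, 2] + bbox[2]
    out[[length(out) + 1L]] <- structure(
      list(label = length(out) + 1L,
           pixels = cbind(row = r1 - 1L, col = c1 - 1L),
           boundary = outer,
           bbox = bbox,
           area_px = length(pos)),
      class = "roi_object")
  }
  out
}

#' @export
print.roi_object <- function(x, ...) {
  cat(sprintf("<roi_object> label %d: %d px, bbox rows %d-%d cols %d-%d\n",
              x$label, x$area_px, x$bbox[1], x$bbox[3], x$bbox[2], x$bbox[4]))
  invisible(x)
}

#' Intensity surface reconstruction
#'
#' Reconstructs the 3D surface representation of an image: the height at
#' each pixel is its intensity on the 256-level scale (0--255). The grid is
#' suitable for surface rendering (see the `plot` method).
#'
#' @param image A [calibrated_image()].
#' @return An object of class `surface_grid` with element `heights`, a
#'   matrix of the same dimensions as the image.
#' @export
surface_plot <- function(image) {
  img <- if (inherits(image, "calibrated_image")) image else
    stop("`image` must be a calibrated_image")
  structure(list(heights = img$grid, pixel_size = img$pixel_size),
            class = "surface_grid")
}

#' @export
print.surface_grid <- function(x, ...) {
  cat(sprintf("<surface_grid> %d x %d, heights [%d, %d] on 0-255 scale\n",
              nrow(x$heights), ncol(x$heights),
              min(x$heights), max(x$heights)))
  invisible(x)
}

#' @export
plot.surface_grid <- function(x, max_cells = 150L, theta = 30, phi = 30, ...) {
  h <- x$heights
  # downsample for rendering speed on full-frame images
  step <- max(1L, ceiling(max(dim(h)) / max_cells))
  h <- h[seq(1, nrow(h), by = step), seq(1, ncol(h), by = step), drop = FALSE]
  graphics::persp(z = h, theta = theta, phi = phi, zlim = c(0, 255),
                  xlab = "row", ylab = "col", zlab = "intensity",
                  border = NA, col = "grey80", shade = 0.6, ...)
  invisible(x)
}
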