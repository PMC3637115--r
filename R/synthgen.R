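#' Specification of one synthetic cell-shaped fluorescent object
#'
#' Describes an object of one of the two geometry classes observed in
#' cultured fibroblasts: `"spindle"` (elongated, Y-like, low circularity --
#' the control morphology) or `"signet"` (rounded, high circularity -- the
#' celiac morphology). The rendered mask realizes the requested feret
#' diameter and circularity index up to discretization.
#'
#' @param geometry_class `"spindle"` or `"signet"`.
#' @param target_feret Target maximum feret diameter in micrometres (> 0).
#' @param target_circularity Target circularity index in (0, 1]; spindle
#'   specs must be below 0.45 and signet specs at or above 0.45 (the class
#'   boundary between elongated and rounded morphologies).
#' @param centre Object centre `(x, y)` in micrometres within the scene.
#' @param orientation Rotation of the shape's major axis in radians.
#' @param peak_intensity Peak rendered intensity, an integer in 1--255.
#' @return An object of class `shape_spec`.
#' @export
shape_spec <- function(geometry_class, target_feret, target_circularity,
                       centre = c(0, 0), orientation = 0,
                       peak_intensity = 200L) {
  geometry_class <- match.arg(geometry_class, c("spindle", "signet"))
  if (!is.numeric(target_feret) || target_feret <= 0)
    stop("`target_feret` must be positive")
  if (target_circularity <= 0 || target_circularity > 1)
    stop("`target_circularity` must be in (0, 1]")
  if (geometry_class == "spindle" && target_circularity >= 0.45)
    stop("spindle specs must have target_circularity < 0.45")
  if (geometry_class == "signet" && target_circularity < 0.45)
    stop("signet specs must have target_circularity >= 0.45")
  if (peak_intensity < 1 || peak_intensity > 255)
    stop("`peak_intensity` must be in 1..255")
  if (length(centre) != 2L || anyNA(centre))
    stop("`centre` must be an (x, y) position in um")
  structure(list(geometry_class = geometry_class,
                 target_feret = target_feret,
                 target_circularity = target_circularity,
                 centre = as.numeric(centre),
                 orientation = as.numeric(orientation),
                 peak_intensity = as.integer(round(peak_intensity))),
            class = "shape_spec")
}

# Boundary sample of the superellipse |x/a|^n + |y/b|^n = 1.
superellipse_pts <- function(a, b, nexp, m = 720L) {
  t <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  cbind(x = a * sign(cos(t)) * abs(cos(t))^(2 / nexp),
        y = b * sign(sin(t)) * abs(sin(t))^(2 / nexp))
}

# Find superellipse semi-axes whose continuous outline realizes the target
# feret L and orthogonal extent W (a raw superellipse with exponent > 2
# bulges beyond its semi-axis along the diagonal). Deterministic fixed-point
# iteration on the sampled outline.
calibrate_superellipse <- function(L, W, nexp = 2.5) {
  a <- L / 2; b <- W / 2
  for (k in 1:6) {
    P <- superellipse_pts(a, b, nexp)
    fo <- feret_diameters(cbind(row = P[, "y"], col = P[, "x"]),
                          pixel_size = 1)
    a <- a * L / fo[["feret"]]
    b <- b * W / fo[["orthogonal"]]
  }
  c(a = a, b = b)
}

#' Render one synthetic cell mask
#'
#' Builds a binary mask realizing a [shape_spec()] at the given resolution.
#' Signet objects are rounded superellipses (exponent 2.5, semi-axes
#' calibrated so that the realized feret and circularity hit their
#' targets); spindle objects are bipolar bodies with polynomially tapering
#' arms and, by default, a third short arm giving the Y-like outline of a
#' migration-ready fibroblast. Tips sit at exactly `target_feret` apart and
#' the extent orthogonal to the tip axis equals
#' `target_circularity * target_feret`, so the realized indices match the
#' targets up to pixelation.
#'
#' @param spec A [shape_spec()].
#' @param pixel_size Pixel size in micrometres; the target feret must span
#'   at least 8 pixels at this resolution.
#' @param arms For spindle shapes, 2 (bipolar) or 3 (Y-like, default).
#' @return A list with `mask` (0/1 integer matrix, a single 8-connected
#'   component), `record` (the realized [measure_objects()] row for the
#'   mask) and `origin` (1-based (row, col) index of the shape centre
#'   within the mask, used to place it in a scene).
#' @export
make_cell_mask <- function(spec, pixel_size, arms = 3L) {
  if (!inherits(spec, "shape_spec")) stop("`spec` must be a shape_spec")
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  L <- spec$target_feret / pixel_size
  if (L < 8)
    stop("resolution error: target feret spans fewer than 8 pixels")
  W <- spec$target_circularity * L
  R <- ceiling(L / 2) + 3L
  coord <- seq(-R, R)
  n <- length(coord)
  x <- matrix(coord, n, n, byrow = TRUE)   # col offset
  y <- matrix(coord, n, n)                 # row offset
  th <- spec$orientation
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  if (spec$geometry_class == "signet") {
    ab <- calibrate_superellipse(L, W)
    inside <- (abs(u) / ab[["a"]])^2.5 + (abs(v) / ab[["b"]])^2.5 <= 1
  } else {
    if (!arms %in% c(2L, 3L)) stop("`arms` must be 2 or 3")
    wmin <- 0.75
    prof <- (W / 2) * pmax(1 - (2 * u / L)^2, 0)^1.5
    inside <- abs(u) <= L / 2 & abs(v) <= pmax(prof, wmin)
    if (arms == 3L) {
      vtip <- 0.95 * (W / 2)
      u3 <- 0.15 * L
      frac <- v / vtip
      wa <- pmax(0.12 * L * (1 - frac), 0.9)
      inside <- inside |
        (v >= 0 & v <= vtip & abs(u - u3 * frac) <= wa & abs(u) <= L / 2)
    }
  }
  mask <- matrix(as.integer(inside), n, n)
  keep_r <- range(which(rowSums(mask) > 0))
  keep_c <- range(which(colSums(mask) > 0))
  origin <- c(row = R + 1L - keep_r[1] + 1L, col = R + 1L - keep_c[1] + 1L)
  mask <- mask[keep_r[1]:keep_r[2], keep_c[1]:keep_c[2], drop = FALSE]
  lab <- label_components(mask)
  if (max(lab) != 1L)
    stop("internal error: rendered mask is not a single component")
  rois <- detect_objects(mask, min_size = 1L)
  rec <- measure_objects(calibrated_image(mask * 255L, pixel_size), rois)
  list(mask = mask, record = rec[1L, , drop = FALSE], origin = origin)
}

#' Ground truth for a synthetic still scene
#'
#' @param shape_specs List of [shape_spec()]s.
#' @param image_dims Image size as `(rows, cols)` in pixels; the default
#'   matches the 764 x 560 stored-image matrix (764 wide, 560 tall).
#' @param pixel_size Pixel size in micrometres (default 0.5 um/px, making
#'   35--90 um cells span realistic pixel counts).
#' @param seed Integer seed used when the scene is rendered.
#' @return An object of class `scene_truth`.
#' @export
scene_truth <- function(shape_specs, image_dims = c(560L, 764L),
                        pixel_size = 0.5, seed = 1L) {
  if (!all(vapply(shape_specs, inherits, logical(1), "shape_spec")))
    stop("`shape_specs` must be a list of shape_spec objects")
  if (pixel_size <= 0) stop("`pixel_size` must be positive")
  for (sp in shape_specs) {
    half <- sp$target_feret / 2 + 2 * pixel_size
    if (sp$centre[1] < half || sp$centre[2] < half ||
        sp$centre[1] > (image_dims[2] - 1) * pixel_size - half ||
        sp$centre[2] > (image_dims[1] - 1) * pixel_size - half)
      stop("shape footprint extends beyond image bounds")
  }
  structure(list(shape_specs = shape_specs,
                 image_dims = as.integer(image_dims),
                 pixel_size = pixel_size, seed = as.integer(seed)),
            class = "scene_truth")
}

#' Render a synthetic still scene
#'
#' Renders every object of a [scene_truth()] onto a noisy background:
#' additive truncated-Gaussian background (clipped to 0--255) plus uniform
#' object intensity at each spec's peak with mild Gaussian texture. Objects
#' must be discrete: overlapping footprints raise an error.
#'
#' @param truth A [scene_truth()].
#' @param background_mean,background_sd Background intensity parameters;
#'   `background_mean` must lie below every spec's peak intensity.
#' @param seed Seed for the rendering noise; defaults to `truth$seed`.
#'   Identical truth and seed give a bit-identical image.
#' @return A [calibrated_image()]. The attribute `"truth"` holds a data
#'   frame of realized per-object ground truth (centre, area, feret,
#'   circularity) and the attribute `"footprints"` the list of linear pixel
#'   indices of each rendered object.
#' @export
render_scene <- function(truth, background_mean = 10, background_sd = 3,
                         seed = NULL) {
  if (!inherits(truth, "scene_truth")) stop("`truth` must be a scene_truth")
  peaks <- vapply(truth$shape_specs, function(s) s$peak_intensity, numeric(1))
  if (length(peaks) && (background_mean < 0 || background_mean >= min(peaks)))
    stop("`background_mean` must be in [0, min peak_intensity)")
  seed <- seed %||% truth$seed
  dims <- truth$image_dims
  ps <- truth$pixel_size
  with_seed(seed, {
    grid <- matrix(clip255(round(stats::rnorm(prod(dims), background_mean,
                                              background_sd))),
                   dims[1], dims[2])
    occupied <- matrix(FALSE, dims[1], dims[2])
    truth_rows <- list(); footprints <- list()
    for (i in seq_along(truth$shape_specs)) {
      sp <- truth$shape_specs[[i]]
      mc <- make_cell_mask(sp, ps)
      r0 <- round(sp$centre[2] / ps) + 1L - (mc$origin[["row"]] - 1L)
      c0 <- round(sp$centre[1] / ps) + 1L - (mc$origin[["col"]] - 1L)
      nr <- nrow(mc$mask); nc <- ncol(mc$mask)
      if (r0 < 1L || c0 < 1L || r0 + nr - 1L > dims[1] ||
          c0 + nc - 1L > dims[2])
        stop(sprintf("object %d footprint extends beyond image bounds", i))
      sel <- which(mc$mask == 1L)
      rr <- ((sel - 1L) %% nr) + r0
      ccc <- ((sel - 1L) %/% nr) + c0
      lin <- (ccc - 1L) * dims[1] + rr
      if (any(occupied[lin]))
        stop(sprintf("object %d overlaps another object; objects must be discrete", i))
      occupied[lin] <- TRUE
      grid[lin] <- clip255(round(sp$peak_intensity +
                                   stats::rnorm(length(lin), 0, 4)))
      footprints[[i]] <- lin
      truth_rows[[i]] <- data.frame(
        id = i, geometry_class = sp$geometry_class,
        centre_x_um = sp$centre[1], centre_y_um = sp$centre[2],
        area_px = length(lin),
        feret_um = mc$record$feret_um,
        circularity = mc$record$circularity)
    }
    img <- calibrated_image(grid, ps)
    attr(img, "truth") <- do.call(rbind, truth_rows)
    attr(img, "footprints") <- footprints
    img
  })
}

#' Draw random non-overlapping shape specifications
#'
#' Convenience generator for validation scenes: samples `n` specs of one
#' geometry class at the default class parameter ranges (feret 30--60 um;
#' circularity 0.15--0.35 for spindle, 0.55--0.90 for signet; peak
#' intensity 150--220) with centres placed by rejection so that footprints
#' stay inside the image and do not touch.
#'
#' @param n Number of objects.
#' @param geometry_class `"spindle"` or `"signet"`.
#' @param image_dims,pixel_size Scene geometry (defaults as [scene_truth()]).
#' @param seed Integer seed.
#' @param feret_range,circularity_range,peak_range Optional overrides of
#'   the class parameter ranges.
#' @return A list of [shape_spec()]s.
#' @export
sample_shape_specs <- function(n, geometry_class,
                               image_dims = c(560L, 764L), pixel_size = 0.5,
                               seed = 1L, feret_range = c(30, 60),
                               circularity_range = NULL,
                               peak_range = c(150, 220)) {
  geometry_class <- match.arg(geometry_class, c("spindle", "signet"))
  circularity_range <- circularity_range %||%
    if (geometry_class == "spindle") c(0.15, 0.35) else c(0.55, 0.90)
  with_seed(seed, {
    specs <- list()
    centres <- matrix(numeric(0), 0, 2)
    ferets <- numeric(0)
    tries <- 0L
    while (length(specs) < n) {
      tries <- tries + 1L
      if (tries > 5000L)
        stop("could not place all objects without overlap; reduce n or feret")
      fer <- stats::runif(1, feret_range[1], feret_range[2])
      half <- fer / 2 + 3 * pixel_size
      cx <- stats::runif(1, half, (image_dims[2] - 1) * pixel_size - half)
      cy <- stats::runif(1, half, (image_dims[1] - 1) * pixel_size - half)
      if (nrow(centres) > 0) {
        d <- sqrt((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2)
        if (any(d < (ferets + fer) / 2 + 4)) next
      }
      specs[[length(specs) + 1L]] <- shape_spec(
        geometry_class, fer,
        stats::runif(1, circularity_range[1], circularity_range[2]),
        centre = c(cx, cy),
        orientation = stats::runif(1, 0, 2 * pi),
        peak_intensity = round(stats::runif(1, peak_range[1], peak_range[2])))
      centres <- rbind(centres, c(cx, cy))
      ferets <- c(ferets, fer)
    }
    specs
  })
}

#' Specification of a synthetic motility experiment
#'
#' Parameters of the persistent random walk used to emulate fibroblast
#' nucleus movement over a 72-hour recording at 10-minute frame cadence.
#' Cells take one step per 12-hour segment with truncated-normal length,
#' directionally correlated between consecutive segments; positions are
#' interpolated linearly to the frame cadence.
#'
#' @param n_cells Number of cells in the field (>= 1).
#' @param duration Recording length in hours (default 72).
#' @param frame_interval Frame cadence in minutes (default 10).
#' @param step_mean,step_sd Mean and SD of the per-12-h step length in
#'   micrometres; over a 72-h recording the expected true path length is
#'   `6 * step_mean`.
#' @param persistence Directional correlation between consecutive segments
#'   in `[0, 1]`: 1 gives straight-line motion, 0 uncorrelated headings.
#' @param nucleus_radius Rendered nucleus radius in micrometres.
#' @return An object of class `motility_spec`.
#' @export
motility_spec <- function(n_cells, duration = 72, frame_interval = 10,
                          step_mean = 37, step_sd = 14.7,
                          persistence = 0.3, nucleus_radius = 5) {
  if (n_cells < 1) stop("`n_cells` must be >= 1")
  if (duration <= 0) stop("`duration` must be positive")
  if (frame_interval <= 0) stop("`frame_interval` must be positive")
  if (step_mean <= 0) stop("`step_mean` must be positive")
  if (step_sd < 0) stop("`step_sd` must be >= 0")
  if (persistence < 0 || persistence > 1)
    stop("`persistence` must be in [0, 1]")
  if (nucleus_radius <= 0) stop("`nucleus_radius` must be positive")
  structure(list(n_cells = as.integer(n_cells), duration = duration,
                 frame_interval = frame_interval, step_mean = step_mean,
                 step_sd = step_sd, persistence = persistence,
                 nucleus_radius = nucleus_radius),
            class = "motility_spec")
}

# Fold a coordinate into [lo, hi] by reflection (triangle map).
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Generate a synthetic time-lapse sequence with ground truth
#'
#' Simulates nucleus trajectories under a [motility_spec()] and prepares a
#' renderable frame sequence. Trajectories follow the persistent random
#' walk of the spec; cells start in a central region of the field (inset
#' 150 um from the borders when the field allows) and reflect off the
#' borders so they never leave the frame. True positions are recorded at
#' every frame; frames are rendered on demand by [render_frame()] so that
#' long sequences stay cheap.
#'
#' @param spec A [motility_spec()].
#' @param dims Frame size `(rows, cols)` in pixels (default 560 x 764).
#' @param pixel_size Pixel size in micrometres (default 1.0 um/px, the
#'   coarser sampling of 10x time-lapse acquisition).
#' @param seed Integer seed; identical spec and seed give identical output.
#' @param background_mean,background_sd,nucleus_peak Rendering intensities.
#' @return An object of class `timelapse` with elements `times_h` (frame
#'   times; `floor(duration * 60 / frame_interval) + 1` frames),
#'   `positions` (`n_frames x n_cells x 2` array of true (x, y) in um),
#'   and the rendering parameters.
#' @export
make_timelapse <- function(spec, dims = c(560L, 764L), pixel_size = 1.0,
                           seed = 1L, background_mean = 10,
                           background_sd = 3, nucleus_peak = 200L) {
  if (!inherits(spec, "motility_spec"))
    stop("`spec` must be a motility_spec")
  if (spec$nucleus_radius / pixel_size < 2)
    stop("resolution error: nucleus radius spans fewer than 2 pixels")
  n_frames <- floor(spec$duration * 60 / spec$frame_interval) + 1L
  times_h <- seq_len(n_frames - 1L) * spec$frame_interval / 60
  times_h <- c(0, times_h)
  width <- (dims[2] - 1) * pixel_size
  height <- (dims[1] - 1) * pixel_size
  margin <- spec$nucleus_radius + pixel_size
  with_seed(seed, {
    inset <- min(150, 0.35 * min(width, height))
    sep <- min(90, 0.8 * sqrt((width - 2 * inset) * (height - 2 * inset) /
                                max(spec$n_cells, 1)))
    starts <- matrix(NA_real_, spec$n_cells, 2)
    placed <- 0L; tries <- 0L
    while (placed < spec$n_cells) {
      tries <- tries + 1L
      p <- c(stats::runif(1, inset, width - inset),
             stats::runif(1, inset, height - inset))
      ok <- placed == 0L ||
        all(sqrt(rowSums((starts[seq_len(placed), , drop = FALSE] -
                            matrix(p, placed, 2, byrow = TRUE))^2)) >= sep)
      if (ok || tries > 5000L) {
        placed <- placed + 1L
        starts[placed, ] <- p
      }
    }
    seg_times <- seq(0, spec$duration, by = 12)
    if (seg_times[length(seg_times)] < spec$duration)
      seg_times <- c(seg_times, spec$duration)
    n_seg <- length(seg_times) - 1L
    positions <- array(NA_real_, c(n_frames, spec$n_cells, 2))
    for (cell in seq_len(spec$n_cells)) {
      steps <- rnorm_trunc(n_seg, spec$step_mean, spec$step_sd, lower = 0)
      steps <- steps * diff(seg_times) / 12
      ang <- numeric(n_seg)
      ang[1] <- stats::runif(1, 0, 2 * pi)
      if (n_seg > 1)
        for (k in 2:n_seg)
          ang[k] <- ang[k - 1] +
            (1 - spec$persistence) * stats::runif(1, -pi, pi)
      way <- matrix(NA_real_, n_seg + 1L, 2)
      way[1, ] <- starts[cell, ]
      for (k in seq_len(n_seg))
        way[k + 1L, ] <- way[k, ] + steps[k] * c(cos(ang[k]), sin(ang[k]))
      px <- stats::approx(seg_times, way[, 1], xout = times_h)$y
      py <- stats::approx(seg_times, way[, 2], xout = times_h)$y
      positions[, cell, 1] <- reflect_into(px, margin, width - margin)
      positions[, cell, 2] <- reflect_into(py, margin, height - margin)
    }
    frame_seeds <- sample.int(.Machine$integer.max - 1L, n_frames)
    structure(list(times_h = times_h, positions = positions, spec = spec,
                   dims = as.integer(dims), pixel_size = pixel_size,
                   seed = as.integer(seed),
                   background_mean = background_mean,
                   background_sd = background_sd,
                   nucleus_peak = as.integer(nucleus_peak),
                   frame_seeds = frame_seeds),
              class = "timelapse")
  })
}

#' @export
print.timelapse <- function(x, ...) {
  cat(sprintf(
    "<timelapse> %d cells, %d frames (%.0f h at %.0f-min cadence), %d x %d px\n",
    x$spec$n_cells, length(x$times_h), x$spec$duration,
    x$spec$frame_interval, x$dims[1], x$dims[2]))
  invisible(x)
}

#' Render one frame of a synthetic time-lapse
#'
#' Materializes frame `index` of a [make_timelapse()] sequence: truncated-
#' Gaussian background plus one Gaussian nucleus blob per cell at its true
#' sub-pixel position. Deterministic: each frame has its own derived seed.
#'
#' @param tl A `timelapse` object.
#' @param index Frame index (1-based).
#' @return A [calibrated_image()].
#' @export
render_frame <- function(tl, index) {
  if (!inherits(tl, "timelapse")) stop("`tl` must be a timelapse")
  if (index < 1L || index > length(tl$times_h)) stop("frame index out of range")
  dims <- tl$dims; ps <- tl$pixel_size
  r_px <- tl$spec$nucleus_radius / ps
  sigma <- r_px / 1.8
  with_seed(tl$frame_seeds[index], {
    grid <- matrix(stats::rnorm(prod(dims), tl$background_mean,
                                tl$background_sd), dims[1], dims[2])
    cut <- ceiling(2.2 * r_px)
    for (cell in seq_len(tl$spec$n_cells)) {
      cx <- tl$positions[index, cell, 1] / ps   # 0-based col coordinate
      cy <- tl$positions[index, cell, 2] / ps
      rs <- max(1L, floor(cy) - cut + 1L):min(dims[1], ceiling(cy) + cut + 1L)
      cs <- max(1L, floor(cx) - cut + 1L):min(dims[2], ceiling(cx) + cut + 1L)
      d2 <- outer((rs - 1 - cy)^2, (cs - 1 - cx)^2, `+`)
      blob <- tl$nucleus_peak * exp(-d2 / (2 * sigma^2))
      blob[d2 > cut^2] <- 0
      grid[rs, cs] <- grid[rs, cs] + blob
    }
    calibrated_image(clip255(round(grid)), ps)
  })
}

#' True cell tracks of a synthetic time-lapse
#'
#' @param tl A `timelapse` object.
#' @param interval_h Sampling interval in hours (default 12, the canonical
#'   tracking cadence).
#' @return A `cell_tracks` data frame (`cell_id`, `time_h`, `x_um`,
#'   `y_um`) of the generator's ground-truth positions.
#' @export
truth_tracks <- function(tl, interval_h = 12) {
  idx <- sample_frames(tl$times_h, interval_h,
                       frame_interval_min = tl$spec$frame_interval)
  out <- do.call(rbind, lapply(seq_len(tl$spec$n_cells), function(cell) {
    data.frame(cell_id = cell, time_h = tl$times_h[idx],
               x_um = tl$positions[idx, cell, 1],
               y_um = tl$positions[idx, cell, 2])
  }))
  class(out) <- c("cell_tracks", "data.frame")
  out
}

#' Sample measured values for a group
#'
#' Draws `n` values from a normal law truncated to
#' `[lower_bound, upper_bound]`, the model used for simulated group
#' measurements (for physically bounded quantities such as circularity in
#' (0, 1] or positive areas).
#'
#' @param mean,sd Distribution parameters (`sd >= 0`; `sd = 0` gives `n`
#'   copies of `mean`).
#' @param n Number of values (>= 2).
#' @param lower_bound,upper_bound Truncation bounds; must bracket `mean`.
#' @param seed Optional integer seed (`NULL` draws from the current RNG
#'   stream).
#' @return Numeric vector of length `n`.
#' @examples
#' sample_group_measurements(0.60, 0.11, 12, 0, 1, seed = 1)
#' @export
sample_group_measurements <- function(mean, sd, n, lower_bound = -Inf,
                                      upper_bound = Inf, seed = NULL) {
  if (sd < 0) stop("`sd` must be >= 0")
  if (n < 2) stop("`n` must be >= 2")
  if (!(lower_bound < mean && mean < upper_bound))
    stop("parameter error: bounds must bracket the mean")
  with_seed(seed, rnorm_trunc(n, mean, sd, lower_bound, upper_bound))
}
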