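#' Select frames at a fixed sampling interval
#'
#' Picks the frames at t = 0, `interval_h`, 2 `interval_h`, ... from a frame
#' stream captured at a fixed cadence; for the canonical 72-h recording at
#' 10-minute cadence sampled every 12 h this returns 7 frames.
#'
#' @param x A `timelapse` object or a numeric vector of frame times in
#'   hours.
#' @param interval_h Sampling interval in hours; must be a whole multiple
#'   of the frame cadence and divide the recording length, so that the
#'   final frame is sampled and complete tracks span the full recording.
#' @param frame_interval_min Frame cadence in minutes; taken from the
#'   `timelapse` when `x` is one.
#' @return Integer vector of frame indices (1-based).
#' @examples
#' tl_times <- seq(0, 72, by = 10 / 60)
#' sample_frames(tl_times, 12, frame_interval_min = 10)
#' @export
sample_frames <- function(x, interval_h, frame_interval_min = NULL) {
  if (inherits(x, "timelapse")) {
    times <- x$times_h
    frame_interval_min <- x$spec$frame_interval
  } else {
    times <- x
    if (is.null(frame_interval_min))
      stop("`frame_interval_min` is required when `x` is a time vector")
  }
  ratio <- interval_h * 60 / frame_interval_min
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("parameter error: `interval_h` is not a multiple of the frame cadence")
  duration <- max(times) - min(times)
  nsteps <- duration / interval_h
  if (abs(nsteps - round(nsteps)) > 1e-9)
    stop("parameter error: `interval_h` is not a multiple of the recording length")
  step <- as.integer(round(ratio))
  seq(1L, length(times), by = step)
}

#' Movie-time compression factor
#'
#' Hours of culture represented by one second of the accelerated movie:
#' a 72-h recording compressed into a 40-s movie gives 1.8 h per second.
#'
#' @param duration_h Recorded culture time in hours.
#' @param movie_seconds Length of the accelerated movie in seconds.
#' @return Hours of culture per movie second.
#' @examples
#' movie_compression(72, 40)
#' @export
movie_compression <- function(duration_h, movie_seconds) {
  if (duration_h <= 0 || movie_seconds <= 0)
    stop("durations must be positive")
  duration_h / movie_seconds
}

#' Detect nucleus centroids in a frame
#'
#' Thresholds the frame with [auto_threshold()], detects blobs with
#' [detect_objects()] at a nucleus-scale minimum size, and returns the
#' intensity-weighted centroid of each blob in physical units.
#'
#' Nuclei cover a tiny fraction of a full frame, and a single global Otsu
#' split on such images can lock onto the background noise instead of the
#' sparse bright class. When the split fails [auto_threshold()]'s class-
#' separation check, the threshold is therefore re-estimated recursively on
#' the pixels above the current level (multi-level Otsu) until a
#' well-separated bright class emerges or the histogram is exhausted.
#' A blob well above the typical blob area most likely merges two touching
#' nuclei and triggers a warning.
#'
#' @param frame A [calibrated_image()].
#' @param min_size Minimum blob size in pixels (default 10).
#' @return An n x 2 matrix with columns `x_um`, `y_um` (empty when nothing
#'   is detected), with the blob pixel areas as attribute `"area_px"`.
#' @export
detect_nuclei <- function(frame, min_size = 10L) {
  if (!inherits(frame, "calibrated_image"))
    stop("`frame` must be a calibrated_image")
  th <- tryCatch(auto_threshold(frame), error = function(e) NULL)
  empty <- matrix(numeric(0), 0, 2,
                  dimnames = list(NULL, c("x_um", "y_um")))
  if (is.null(th)) return(empty)
  level <- th$level
  signal <- th$signal
  g <- frame$grid
  depth <- 0L
  while (!signal && depth < 8L) {
    depth <- depth + 1L
    sub <- g[g > level]
    if (length(sub) == 0L || length(unique(sub)) < 2L) return(empty)
    res <- tryCatch(auto_threshold(matrix(sub, ncol = 1L)),
                    error = function(e) NULL)
    if (is.null(res)) return(empty)
    level <- res$level
    signal <- res$signal
  }
  if (!signal) return(empty)
  rois <- detect_objects(g > level, min_size = min_size)
  if (length(rois) == 0L) return(empty)
  ps <- frame$pixel_size
  cents <- t(vapply(rois, function(roi) {
    w <- as.numeric(frame$grid[roi$pixels + 1L])
    c(sum(roi$pixels[, "col"] * w) / sum(w) * ps,
      sum(roi$pixels[, "row"] * w) / sum(w) * ps)
  }, numeric(2)))
  colnames(cents) <- c("x_um", "y_um")
  areas <- vapply(rois, function(r) r$area_px, numeric(1))
  # two equal nuclei fused at under two radii apart cover ~1.5x the single
  # blob area, so a 1.4x excess over the typical blob flags a likely merger
  typical <- if (length(areas) == 2L) min(areas) else stats::median(areas)
  if (length(areas) >= 2L && any(areas > 1.4 * typical))
    warning("possible merged nuclei: blob(s) well above the typical area")
  attr(cents, "area_px") <- areas
  cents
}

#' Link detections across timepoints into cell tracks
#'
#' Greedy nearest-pair assignment between consecutive timepoints: candidate
#' pairs within the gate are accepted in order of increasing distance (ties
#' broken by lower track id, then lower detection index), each detection
#' and track used at most once. Tracks missing a match at any timepoint
#' terminate; only tracks spanning every timepoint are returned, mirroring
#' cells followed for the full recording.
#'
#' @param centroid_lists List (one element per sampled timepoint) of n x 2
#'   matrices as returned by [detect_nuclei()].
#' @param times_h Numeric vector of the sampled times in hours.
#' @param gate Maximum linking distance in micrometres per sampling step
#'   (default 100, about three times the largest per-segment mean step).
#' @return A `cell_tracks` data frame (`cell_id`, `time_h`, `x_um`,
#'   `y_um`) containing the complete tracks; empty when the first
#'   timepoint has no detections.
#' @export
link_tracks <- function(centroid_lists, times_h, gate = 100) {
  if (length(centroid_lists) < 2L)
    stop("at least two timepoints are required")
  if (length(centroid_lists) != length(times_h))
    stop("`centroid_lists` and `times_h` lengths differ")
  if (gate <= 0) stop("`gate` must be positive")
  first <- centroid_lists[[1L]]
  empty <- data.frame(cell_id = integer(0), time_h = numeric(0),
                      x_um = numeric(0), y_um = numeric(0))
  class(empty) <- c("cell_tracks", "data.frame")
  if (is.null(first) || nrow(first) == 0L) return(empty)
  n0 <- nrow(first)
  paths <- lapply(seq_len(n0), function(i) first[i, , drop = FALSE])
  alive <- rep(TRUE, n0)
  for (t in 2L:length(centroid_lists)) {
    cur <- centroid_lists[[t]]
    live <- which(alive)
    if (is.null(cur) || nrow(cur) == 0L || length(live) == 0L) {
      alive[] <- FALSE
      break
    }
    ends <- t(vapply(paths[live], function(p) as.numeric(p[nrow(p), ]),
                     numeric(2)))
    d <- sqrt(outer(ends[, 1], cur[, 1], `-`)^2 +
                outer(ends[, 2], cur[, 2], `-`)^2)
    cand <- which(d <= gate, arr.ind = TRUE)
    matched_tr <- logical(length(live))
    matched_pt <- logical(nrow(cur))
    if (nrow(cand) > 0L) {
      ord <- order(d[cand], live[cand[, 1]], cand[, 2])
      for (k in ord) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (matched_tr[i] || matched_pt[j]) next
        matched_tr[i] <- TRUE; matched_pt[j] <- TRUE
        paths[[live[i]]] <- rbind(paths[[live[i]]], cur[j, , drop = FALSE])
      }
    }
    alive[live[!matched_tr]] <- FALSE
  }
  keep <- which(alive)
  if (length(keep) == 0L) return(empty)
  out <- do.call(rbind, lapply(seq_along(keep), function(k) {
    p <- paths[[keep[k]]]
    data.frame(cell_id = k, time_h = times_h,
               x_um = p[, 1], y_um = p[, 2])
  }))
  rownames(out) <- NULL
  class(out) <- c("cell_tracks", "data.frame")
  out
}

#' @export
print.cell_tracks <- function(x, ...) {
  cat(sprintf("<cell_tracks> %d cell(s) x %d timepoint(s)\n",
              length(unique(x$cell_id)), length(unique(x$time_h))))
  invisible(x)
}

#' @rdname link_tracks
#' @param x A `cell_tracks` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cell_tracks <- function(x, ...) {
  graphics::plot(x$x_um, x$y_um, type = "n", xlab = "x (um)",
                 ylab = "y (um)", asp = 1, ylim = rev(range(x$y_um)), ...)
  for (id in unique(x$cell_id)) {
    p <- x[x$cell_id == id, ]
    graphics::lines(p$x_um, p$y_um, col = id)
    graphics::points(p$x_um[1], p$y_um[1], pch = 16, col = id)
  }
  invisible(x)
}

track_matrix <- function(track) {
  if (is.data.frame(track)) {
    track <- track[order(track$time_h), , drop = FALSE]
    as.matrix(track[, c("x_um", "y_um")])
  } else as.matrix(track)
}

#' Total displacement of a tracked cell
#'
#' Path length over the sampled waypoints: the sum of Euclidean distances
#' between consecutive sampled positions of the nucleus.
#'
#' @param track A single-cell track: a data frame with columns `time_h`,
#'   `x_um`, `y_um`, or an ordered n x 2 position matrix in micrometres.
#' @return Total displacement in micrometres.
#' @examples
#' total_displacement(cbind(c(0, 3, 6), c(0, 4, 8)))  # 10
#' @export
total_displacement <- function(track) {
  P <- track_matrix(track)
  if (nrow(P) < 2L) stop("a track needs at least two positions")
  sum(sqrt(rowSums(diff(P)^2)))
}

#' Net start-to-end displacement of a tracked cell
#'
#' @inheritParams total_displacement
#' @return Straight-line distance between first and last position (um).
#' @export
net_displacement <- function(track) {
  P <- track_matrix(track)
  if (nrow(P) < 2L) stop("a track needs at least two positions")
  sqrt(sum((P[nrow(P), ] - P[1L, ])^2))
}

#' Mean velocity of a tracked cell
#'
#' Total displacement divided by elapsed time.
#'
#' @param track A single-cell track data frame (`time_h`, `x_um`, `y_um`).
#' @return Velocity in micrometres per hour.
#' @export
velocity <- function(track) {
  if (!is.data.frame(track) || is.null(track$time_h))
    stop("`track` must be a data frame with a time_h column")
  el <- max(track$time_h) - min(track$time_h)
  if (el <= 0) stop("parameter error: track duration must be positive")
  total_displacement(track) / el
}

#' Per-cell motility summary
#'
#' @param tracks A `cell_tracks` data frame from [link_tracks()] or
#'   [truth_tracks()].
#' @return Data frame with one row per cell: `cell_id`,
#'   `total_displacement_um`, `net_displacement_um`, `velocity_um_per_h`.
#' @export
summarize_tracks <- function(tracks) {
  ids <- unique(tracks$cell_id)
  do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$cell_id == id, ]
    data.frame(cell_id = id,
               total_displacement_um = total_displacement(tr),
               net_displacement_um = net_displacement(tr),
               velocity_um_per_h = velocity(tr))
  }))
}

#' Shape indices of tracked cells over time
#'
#' Re-measures the morphometric descriptors of each tracked cell at
#' selected times of the recording (canonically 0, 36 and 72 h): each
#' requested frame is segmented and measured, and objects are joined to
#' track identities by nearest centroid.
#'
#' @param frames Named or unnamed list of [calibrated_image()] frames, one
#'   per entry of `frame_times_h`.
#' @param frame_times_h Times (hours) of the supplied frames.
#' @param times Times at which shapes are requested (default `c(0, 36,
#'   72)`); each must be present in `frame_times_h`.
#' @param tracks A `cell_tracks` data frame giving the cell positions.
#' @param min_size Minimum object size in pixels for detection.
#' @param max_match Maximum centroid-to-track distance for the identity
#'   join, in micrometres (default 30).
#' @return A data frame of per-cell, per-time morphometric records
#'   (`cell_id`, `time_h` plus the [measure_objects()] columns).
#' @export
shape_timecourse <- function(frames, frame_times_h, times = c(0, 36, 72),
                             tracks, min_size = 10L, max_match = 30) {
  if (!all(times %in% frame_times_h))
    stop("parameter error: requested time(s) missing from the frame stream")
  if (!all(times %in% tracks$time_h))
    stop("parameter error: requested time(s) missing from the tracks")
  out <- list()
  for (tt in times) {
    frame <- frames[[which(frame_times_h == tt)[1L]]]
    th <- auto_threshold(frame)
    rois <- detect_objects(th$mask, min_size = min_size)
    recs <- measure_objects(frame, rois)
    at_t <- tracks[tracks$time_h == tt, ]
    for (k in seq_len(nrow(at_t))) {
      d <- sqrt((recs$centroid_x_um - at_t$x_um[k])^2 +
                  (recs$centroid_y_um - at_t$y_um[k])^2)
      if (length(d) == 0L || min(d) > max_match) next
      row <- recs[which.min(d), , drop = FALSE]
      out[[length(out) + 1L]] <-
        cbind(data.frame(cell_id = at_t$cell_id[k], time_h = tt),
              row[, setdiff(names(row), "label"), drop = FALSE])
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cell_id = integer(0), time_h = numeric(0))
  rownames(res) <- NULL
  res
}

#' Track nuclei through a synthetic or recorded frame sequence
#'
#' Convenience driver for the canonical tracking workflow: sample the
#' frame stream at `interval_h`, detect nuclei in each sampled frame and
#' link them into complete tracks.
#'
#' @param tl A `timelapse` object (frames are rendered on demand), or a
#'   list of [calibrated_image()] frames together with `times_h`.
#' @param times_h Frame times in hours (ignored for a `timelapse`).
#' @param interval_h Sampling interval in hours (default 12).
#' @param gate Linking gate in micrometres (default 100).
#' @param min_size Minimum nucleus blob size in pixels.
#' @return A `cell_tracks` data frame of complete tracks.
#' @export
track_nuclei <- function(tl, times_h = NULL, interval_h = 12, gate = 100,
                         min_size = 10L) {
  if (inherits(tl, "timelapse")) {
    idx <- sample_frames(tl, interval_h)
    frames <- lapply(idx, function(i) render_frame(tl, i))
    st <- tl$times_h[idx]
  } else {
    if (is.null(times_h)) stop("`times_h` required for a frame list")
    idx <- sample_frames(times_h, interval_h,
                         frame_interval_min = diff(times_h[1:2]) * 60)
    frames <- tl[idx]
    st <- times_h[idx]
  }
  cents <- lapply(frames, detect_nuclei, min_size = min_size)
  link_tracks(cents, st, gate = gate)
}
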