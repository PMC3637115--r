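test_that("frame sampling picks the 12-hour waypoints of a 72-h recording", {
  times <- seq(0, 72, by = 10 / 60)
  idx <- sample_frames(times, 12, frame_interval_min = 10)
  expect_identical(idx, seq(1L, 433L, by = 72L))
  expect_length(idx, 7L)
  expect_equal(times[idx], seq(0, 72, by = 12))
  expect_error(sample_frames(times, 7, frame_interval_min = 10),
               "multiple")
})

test_that("movie-time compression converts recording hours to movie seconds", {
  expect_equal(movie_compression(72, 40), 1.8)
  expect_error(movie_compression(0, 40), "positive")
})

test_that("nucleus detection localizes synthetic nuclei to within one pixel", {
  set.seed(91)
  pos <- cbind(runif(15, 30, 170), runif(15, 30, 170))
  # enforce separation so blobs stay discrete
  while (min(dist(pos)) < 25) pos <- cbind(runif(15, 30, 170),
                                           runif(15, 30, 170))
  frame <- render_nuclei_frame(pos, dims = c(200L, 200L), pixel_size = 1)
  cents <- detect_nuclei(frame, min_size = 10)
  expect_identical(nrow(cents), 15L)
  d <- vapply(seq_len(15), function(k)
    min(sqrt((cents[, 1] - pos[k, 1])^2 + (cents[, 2] - pos[k, 2])^2)),
    numeric(1))
  expect_true(all(d < 1))
})

test_that("a blank frame yields no nuclei and near nuclei warn as merged", {
  blank <- calibrated_image(matrix(c(rep(10L, 399), 11L), 20, 20), 1)
  expect_identical(nrow(detect_nuclei(blank, min_size = 5)), 0L)
  two <- render_nuclei_frame(rbind(c(60, 60), c(67, 60), c(140, 140)),
                             dims = c(200L, 200L))
  expect_warning(cents <- detect_nuclei(two, min_size = 10), "merged")
  expect_identical(nrow(cents), 2L)  # the close pair fuses into one blob
})

test_that("greedy linking recovers identities and respects the gate", {
  # three cells drifting right by 10 um per step
  mk <- function(t) cbind(x_um = c(10, 50, 90) + 10 * t,
                          y_um = c(20, 20, 20))
  tracks <- link_tracks(lapply(0:6, mk), times_h = seq(0, 72, by = 12),
                        gate = 100)
  expect_identical(length(unique(tracks$cell_id)), 3L)
  st <- summarize_tracks(tracks)
  expect_equal(st$total_displacement_um, rep(60, 3))
  # stationary cells give zero-length tracks
  stat <- link_tracks(lapply(0:2, function(t) mk(0)),
                      times_h = c(0, 12, 24), gate = 100)
  expect_equal(summarize_tracks(stat)$total_displacement_um, rep(0, 3))
  # a cell vanishing mid-sequence is excluded from the complete tracks
  lists <- list(mk(0), mk(1)[1:2, ], mk(2)[1:2, ])
  part <- link_tracks(lists, times_h = c(0, 12, 24), gate = 100)
  expect_identical(length(unique(part$cell_id)), 2L)
  # displacements beyond the gate break the track
  jump <- list(cbind(x_um = 10, y_um = 10), cbind(x_um = 200, y_um = 10))
  expect_identical(nrow(link_tracks(jump, times_h = c(0, 12), gate = 100)),
                   0L)
  expect_identical(nrow(link_tracks(list(mk(0)[0, ], mk(1)),
                                    times_h = c(0, 12))), 0L)
})

test_that("displacement and velocity arithmetic", {
  tr <- data.frame(time_h = c(0, 12, 24), x_um = c(0, 3, 6),
                   y_um = c(0, 4, 8))
  expect_equal(total_displacement(tr), 10)
  expect_equal(net_displacement(tr), 10)
  expect_equal(velocity(tr), 10 / 24)
  expect_equal(total_displacement(cbind(c(5, 5), c(7, 7))), 0)
  tr72 <- data.frame(time_h = seq(0, 72, by = 12),
                     x_um = seq(0, 216, by = 36), y_um = rep(0, 7))
  expect_equal(velocity(tr72), 3.0)
  expect_error(velocity(data.frame(time_h = c(5, 5), x_um = 1:2,
                                   y_um = 1:2)), "duration")
})

test_that("path length dominates net displacement and velocity is exact", {
  set.seed(92)
  for (k in 1:25) {
    tr <- data.frame(time_h = seq(0, 72, by = 12),
                     x_um = cumsum(rnorm(7, 0, 20)),
                     y_um = cumsum(rnorm(7, 0, 20)))
    expect_gte(total_displacement(tr) + 1e-12, net_displacement(tr))
    expect_equal(velocity(tr) * 72, total_displacement(tr))
  }
})

test_that("12-h sampling of a straight-line walk measures the true path length", {
  tl <- make_timelapse(motility_spec(3, step_mean = 25, step_sd = 0,
                                     persistence = 1), seed = 93)
  st <- summarize_tracks(truth_tracks(tl, interval_h = 12))
  expect_equal(st$total_displacement_um, rep(150, 3), tolerance = 1e-9)
})

test_that("the tracker recovers well-separated synthetic cells exactly", {
  n_correct <- 0L; n_total <- 0L; errs <- c()
  for (s in 1:20) {
    tl <- make_timelapse(motility_spec(5, step_mean = 18.83, step_sd = 6.5),
                         seed = 400 + s)
    tracks <- suppressWarnings(track_nuclei(tl))
    tt <- truth_tracks(tl)
    st <- summarize_tracks(tracks)
    stt <- summarize_tracks(tt)
    t0 <- tt[tt$time_h == 0, ]
    r0 <- tracks[tracks$time_h == 0, ]
    for (k in seq_len(nrow(r0))) {
      d <- sqrt((t0$x_um - r0$x_um[k])^2 + (t0$y_um - r0$y_um[k])^2)
      j <- which.min(d)
      n_total <- n_total + 1L
      # identity held if every waypoint stays within the nucleus radius
      rec <- tracks[tracks$cell_id == r0$cell_id[k], ]
      tru <- tt[tt$cell_id == t0$cell_id[j], ]
      if (max(sqrt((rec$x_um - tru$x_um)^2 + (rec$y_um - tru$y_um)^2)) < 5)
        n_correct <- n_correct + 1L
      errs <- c(errs, abs(st$total_displacement_um[st$cell_id == r0$cell_id[k]] -
                            stt$total_displacement_um[stt$cell_id == t0$cell_id[j]]))
    }
  }
  expect_gte(n_total, 90L)
  expect_gte(n_correct / n_total, 0.97)
  expect_lt(mean(errs), 2)  # < 2 px at 1 um/px
})

test_that("shape timecourse joins per-cell records at the requested times", {
  # constant shapes: same scene rendered at 0/36/72 h
  specs <- sample_shape_specs(4, "spindle", seed = 95)
  frames <- lapply(1:3, function(i) render_scene(scene_truth(specs,
                                                             seed = 95)))
  truth <- attr(frames[[1]], "truth")
  tracks <- do.call(rbind, lapply(seq_len(nrow(truth)), function(k)
    data.frame(cell_id = k, time_h = c(0, 36, 72),
               x_um = truth$centre_x_um[k], y_um = truth$centre_y_um[k])))
  tc <- shape_timecourse(frames, c(0, 36, 72), times = c(0, 36, 72),
                         tracks = tracks, min_size = 50)
  expect_identical(nrow(tc), 12L)  # 4 cells x 3 times
  for (k in unique(tc$cell_id)) {
    per <- tc$circularity[tc$cell_id == k]
    expect_lt(diff(range(per)) / mean(per), 0.02)
  }
  expect_error(shape_timecourse(frames, c(0, 36, 72), times = c(0, 24),
                                tracks = tracks), "missing")
})

test_that("programmed elongation shows as decreasing circularity in time", {
  circs <- c(0.42, 0.30, 0.18)
  centre <- c(120, 100)
  frames <- lapply(circs, function(cc) {
    sp <- shape_spec("spindle", 50, cc, centre = centre, orientation = 0.5)
    render_scene(scene_truth(list(sp), image_dims = c(400L, 480L),
                             seed = 96))
  })
  tracks <- data.frame(cell_id = 1, time_h = c(0, 36, 72),
                       x_um = centre[1], y_um = centre[2])
  tc <- shape_timecourse(frames, c(0, 36, 72), times = c(0, 36, 72),
                         tracks = tracks, min_size = 50)
  expect_identical(nrow(tc), 3L)
  expect_true(all(diff(tc$circularity[order(tc$time_h)]) < 0))
})
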