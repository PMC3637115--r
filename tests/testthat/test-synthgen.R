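test_that("shape specs enforce class-consistent circularity", {
  expect_s3_class(shape_spec("spindle", 40, 0.3), "shape_spec")
  expect_s3_class(shape_spec("signet", 40, 0.7), "shape_spec")
  expect_error(shape_spec("spindle", 40, 0.6), "spindle")
  expect_error(shape_spec("signet", 40, 0.3), "signet")
  expect_error(shape_spec("signet", -5, 0.7), "positive")
  expect_error(shape_spec("signet", 40, 0.7, peak_intensity = 300), "255")
})

test_that("rendered masks realize their target feret and circularity", {
  sp <- shape_spec("signet", 35, 0.9, orientation = 0.4)
  mc <- make_cell_mask(sp, pixel_size = 0.5)
  expect_gte(mc$record$feret_um, 33.25)
  expect_lte(mc$record$feret_um, 36.75)
  expect_lt(abs(mc$record$circularity - 0.9), 0.1)
  # identical feret, different class: circularity ordered by class
  spd <- make_cell_mask(shape_spec("spindle", 35, 0.3, orientation = 0.4), 0.5)
  expect_lt(spd$record$circularity, mc$record$circularity)
  expect_error(make_cell_mask(shape_spec("signet", 2, 0.8), pixel_size = 1),
               "resolution")
})

test_that("every mask is a single component with realized indices near target", {
  set.seed(51)
  for (k in 1:20) {
    cls <- if (k %% 2) "spindle" else "signet"
    circ <- if (cls == "spindle") runif(1, 0.15, 0.35) else runif(1, 0.55, 0.9)
    sp <- shape_spec(cls, runif(1, 25, 55), circ,
                     orientation = runif(1, 0, 2 * pi))
    mc <- make_cell_mask(sp, 0.5, arms = sample(2:3, 1))
    expect_length(detect_objects(mc$mask, 1), 1L)
    expect_lt(abs(mc$record$feret_um - sp$target_feret),
              0.05 * sp$target_feret)
    expect_lt(abs(mc$record$circularity - circ), 0.1)
  }
})

test_that("spindle and signet populations separate on measured circularity", {
  set.seed(52)
  n_pairs <- 100
  spindle_circ <- numeric(n_pairs); signet_circ <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    fer <- runif(2, 30, 60)
    spindle_circ[k] <- make_cell_mask(
      shape_spec("spindle", fer[1], runif(1, 0.15, 0.35),
                 orientation = runif(1, 0, 2 * pi)), 0.5)$record$circularity
    signet_circ[k] <- make_cell_mask(
      shape_spec("signet", fer[2], runif(1, 0.55, 0.90),
                 orientation = runif(1, 0, 2 * pi)), 0.5)$record$circularity
  }
  expect_lt(max(spindle_circ), min(signet_circ))
})

test_that("scene rendering is deterministic, bounded and overlap-checked", {
  specs <- sample_shape_specs(4, "signet", seed = 61)
  tr <- scene_truth(specs, seed = 61)
  img1 <- render_scene(tr)
  img2 <- render_scene(tr)
  expect_identical(img1$grid, img2$grid)
  expect_true(all(img1$grid >= 0L & img1$grid <= 255L))
  expect_type(img1$grid[1], "integer")
  # empty scene: pure background, nothing detected
  blank <- render_scene(scene_truth(list(), seed = 3))
  expect_length(detect_objects(auto_threshold(blank)$mask, min_size = 50), 0L)
  # overlapping footprints are rejected
  s1 <- shape_spec("signet", 40, 0.8, centre = c(100, 100))
  s2 <- shape_spec("signet", 40, 0.8, centre = c(110, 100))
  expect_error(render_scene(scene_truth(list(s1, s2), seed = 1)),
               "overlap")
  # out-of-bounds centre rejected at truth construction
  expect_error(scene_truth(list(shape_spec("signet", 40, 0.8,
                                           centre = c(5, 5))), seed = 1),
               "bounds")
})

test_that("time-lapse frame count and determinism follow the spec of the recording", {
  ms <- motility_spec(3, duration = 72, frame_interval = 10,
                      step_mean = 37, step_sd = 14.7)
  tl1 <- make_timelapse(ms, seed = 71)
  tl2 <- make_timelapse(ms, seed = 71)
  expect_length(tl1$times_h, 433L)
  expect_identical(tl1$positions, tl2$positions)
  expect_identical(render_frame(tl1, 5)$grid, render_frame(tl2, 5)$grid)
  expect_error(make_timelapse(motility_spec(2, nucleus_radius = 1),
                              pixel_size = 1), "resolution")
})

test_that("zero step spread with full persistence gives straight-line paths", {
  ms <- motility_spec(4, step_mean = 20, step_sd = 0, persistence = 1)
  tl <- make_timelapse(ms, seed = 72)
  st <- summarize_tracks(truth_tracks(tl))
  expect_equal(st$total_displacement_um, rep(120, 4), tolerance = 1e-9)
  expect_equal(st$net_displacement_um, st$total_displacement_um,
               tolerance = 1e-9)
})

test_that("ground-truth path lengths are calibrated to 6 x step_mean", {
  ms <- motility_spec(500, step_mean = 37, step_sd = 14.7)
  tl <- make_timelapse(ms, seed = 73)
  lens <- summarize_tracks(truth_tracks(tl))$total_displacement_um
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 6 * 37), 3 * se)
})

test_that("group measurement sampling respects bounds, seed and degenerate sd", {
  x <- sample_group_measurements(0.60, 0.11, 12, 0, 1, seed = 81)
  expect_length(x, 12L)
  expect_true(all(x > 0 & x < 1))
  expect_identical(x, sample_group_measurements(0.60, 0.11, 12, 0, 1,
                                                seed = 81))
  expect_equal(sample_group_measurements(5, 0, 6, 0, 10), rep(5, 6))
  expect_error(sample_group_measurements(0.5, 0.1, 10, 0.6, 1), "bracket")
  # draws follow the requested law: mean within 3 SE over a large sample
  y <- sample_group_measurements(0.60, 0.11, 5000, 0, 1, seed = 82)
  expect_lt(abs(mean(y) - 0.60), 3 * 0.11 / sqrt(5000) + 0.003)
})
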