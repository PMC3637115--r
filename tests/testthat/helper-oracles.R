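# Independent oracles used across the suite. These deliberately take the
# slow, direct route (exhaustive scans, dense angle sweeps) so they share no
# code path with the implementations they check.

# Exhaustive Otsu: try every candidate level, compute the between-class
# variance directly from the two pixel populations.
otsu_brute <- function(grid) {
  v <- as.numeric(grid)
  best <- -Inf; best_t <- NA_integer_
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v)
    sb <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) { best <- sb; best_t <- t }
  }
  best_t
}

# Dense rotating projection: caliper width of a point set in every direction;
# the feret diameter is the maximum width, the orthogonal diameter the width
# perpendicular to the maximizing direction.
feret_brute <- function(pts, n_angles = 3600L) {
  ang <- seq(0, pi, length.out = n_angles)
  widths <- vapply(ang, function(a) {
    p <- pts[, 1] * sin(a) + pts[, 2] * cos(a)
    max(p) - min(p)
  }, numeric(1))
  k <- which.max(widths)
  perp <- ang[k] + pi / 2
  p <- pts[, 1] * sin(perp) + pts[, 2] * cos(perp)
  c(feret = widths[k], orthogonal = max(p) - min(p))
}

# Digitized disk / ellipse fixtures (pixel-center inclusion test).
make_disk_mask <- function(r_px, pad = 5L) {
  n <- 2L * ceiling(r_px) + 2L * pad + 1L
  cx <- (n - 1) / 2
  ii <- matrix(0:(n - 1), n, n); jj <- t(ii)
  matrix(as.integer((ii - cx)^2 + (jj - cx)^2 <= r_px^2), n, n)
}

make_ellipse_mask <- function(a_px, b_px, angle = 0, pad = 5L) {
  n <- 2L * ceiling(max(a_px, b_px)) + 2L * pad + 1L
  cx <- (n - 1) / 2
  ii <- matrix(0:(n - 1), n, n); jj <- t(ii)
  u <- (jj - cx) * cos(angle) + (ii - cx) * sin(angle)
  v <- -(jj - cx) * sin(angle) + (ii - cx) * cos(angle)
  matrix(as.integer((u / a_px)^2 + (v / b_px)^2 <= 1), n, n)
}

# Two-pass variance for checking summarize()'s SD.
sd_twopass <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# Render a frame containing Gaussian nucleus blobs at given (x, y) um
# positions, without going through make_timelapse.
render_nuclei_frame <- function(positions_um, dims = c(200L, 200L),
                                pixel_size = 1, radius_um = 5,
                                peak = 200, bg_mean = 10, bg_sd = 3,
                                seed = 1L) {
  set.seed(seed)
  grid <- matrix(stats::rnorm(prod(dims), bg_mean, bg_sd), dims[1], dims[2])
  r_px <- radius_um / pixel_size
  sigma <- r_px / 1.8
  ii <- matrix(0:(dims[1] - 1), dims[1], dims[2])
  jj <- matrix(0:(dims[2] - 1), dims[1], dims[2], byrow = TRUE)
  for (k in seq_len(nrow(positions_um))) {
    cx <- positions_um[k, 1] / pixel_size
    cy <- positions_um[k, 2] / pixel_size
    d2 <- (ii - cy)^2 + (jj - cx)^2
    blob <- peak * exp(-d2 / (2 * sigma^2))
    blob[d2 > (2.2 * r_px)^2] <- 0
    grid <- grid + blob
  }
  calibrated_image(pmin(pmax(round(grid), 0), 255), pixel_size)
}
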