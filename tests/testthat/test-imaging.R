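test_that("a constant stack z-scores to exactly zero", {
  raw <- array(500, dim = c(16, 16, 30))
  zm <- zscore_movie(raw, fps = 2, onset_s = 10, baseline_s = 5)
  expect_true(all(zm$z == 0))
})

test_that("a planted step is recovered at the analytic z after filtering", {
  # one Gaussian spot stepping down at onset over white-noise baseline;
  # oracle: apply the same two convolutions directly to the noiseless step
  # image and compare ROI means
  set.seed(21)
  h <- 40; w <- 40; fps <- 2; n_t <- 40; onset <- 20
  px_um <- 3.3
  xs <- matrix(rep(1:w, each = h), h); ys <- matrix(rep(1:h, w), h)
  spot <- exp(-((xs - 20)^2 + (ys - 20)^2) / (2 * (12 / px_um)^2))
  amp <- -0.01
  noise_sd <- 0.002
  raw <- array(1, dim = c(h, w, n_t))
  for (t in 1:n_t) {
    raw[, , t] <- 1 + amp * spot * (t > onset) + rnorm(h * w, 0, noise_sd)
  }
  zm <- zscore_movie(raw, fps = fps, onset_s = onset / fps, baseline_s = 5,
                     pixel_um = px_um)
  mask <- matrix(0L, h, w); mask[spot > 0.5] <- 1L
  tbl <- quantify_rois(zm, mask, response_window = c(2, 9))
  # oracle: direct convolution of the step with the same kernels
  direct <- glomix:::gauss_blur(amp * spot, 12 / px_um) -
    glomix:::gauss_blur(glomix:::gauss_blur(amp * spot, 40 / px_um), 12 / px_um)
  # analytic s.d. of filtered white noise: the filter chain is linear, so
  # its response to a delta gives the combined kernel and the noise s.d.
  # scales by the kernel's L2 norm
  delta <- matrix(0, h, w); delta[20, 20] <- 1
  keff <- glomix:::gauss_blur(delta - glomix:::gauss_blur(delta, 40 / px_um),
                              12 / px_um)
  filt_noise_sd <- noise_sd * sqrt(sum(keff^2))
  expected_z <- mean(direct[mask == 1L]) / filt_noise_sd
  got <- tbl$mean_z[1]
  expect_lt(abs(got - expected_z) / abs(expected_z), 0.35)
  expect_lt(got, -3)   # clearly detected
})

test_that("ROI quantification equals a naive double loop", {
  set.seed(8)
  z <- array(rnorm(10 * 12 * 30), dim = c(10, 12, 30))
  zm <- structure(list(z = z, fps = 2, onset_frame = 10,
                       baseline_frames = 1:10, pixel_um = 3.3),
                  class = "zscore_movie")
  mask <- matrix(0L, 10, 12)
  mask[2:4, 2:3] <- 1L; mask[7:9, 8:11] <- 2L
  tbl <- quantify_rois(zm, mask, response_window = c(2, 9))
  fr <- 10 + (4:18)
  for (k in 1:2) {
    acc <- c()
    for (i in 1:10) for (j in 1:12) if (mask[i, j] == k) {
      acc <- c(acc, mean(z[i, j, fr]))
    }
    expect_equal(tbl$mean_z[tbl$roi == k], mean(acc))
  }
})

test_that("a uniform z region quantifies to its value", {
  z <- array(-3, dim = c(6, 6, 20))
  zm <- structure(list(z = z, fps = 2, onset_frame = 4, baseline_frames = 1:4,
                       pixel_um = 3.3), class = "zscore_movie")
  mask <- matrix(1L, 6, 6)
  tbl <- quantify_rois(zm, mask, response_window = c(0.5, 3))
  expect_equal(tbl$mean_z, -3)
  expect_error(quantify_rois(zm, matrix(0L, 6, 6)), "No ROI")
})

test_that("detection thresholding zeroes weak responses and is idempotent", {
  expect_equal(apply_detection_threshold(-0.40, -0.42), 0)
  expect_equal(apply_detection_threshold(-0.50, -0.46), -0.50)
  v <- c(-0.3, -0.42, -0.44, 0.2, 0)
  out <- apply_detection_threshold(v, -0.42)
  expect_equal(out, c(0, -0.42, -0.44, 0, 0))
  expect_equal(apply_detection_threshold(out, -0.42), out)  # idempotent
  expect_true(all(abs(out) <= abs(v)))                      # never grows |z|
  # threshold 0 only zeroes positive entries
  expect_equal(apply_detection_threshold(c(-1, 0.5, 0), 0), c(-1, 0, 0))
  tbl <- tibble::tibble(roi = 1:2, mean_z = c(-0.2, -0.9))
  expect_equal(apply_detection_threshold(tbl, -0.42)$mean_z, c(0, -0.9))
  expect_error(apply_detection_threshold(v, 0.1), "threshold")
})

test_that("z-scoring cancels gain and uniform offset of the raw intensity", {
  set.seed(31)
  h <- 12; w <- 12; n_t <- 24
  raw <- array(1, dim = c(h, w, n_t))
  for (t in 1:n_t) raw[, , t] <- 1 + 0.01 * rnorm(h * w) - 0.02 * (t > 12)
  z1 <- zscore_movie(raw, fps = 2, onset_s = 6, baseline_s = 5)
  z2 <- zscore_movie(7 * raw, fps = 2, onset_s = 6, baseline_s = 5)
  expect_equal(z1$z, z2$z, tolerance = 1e-8)
})

test_that("synthetic movies recover atlas amplitudes and respect thresholds", {
  atlas <- small_atlas(12, seed = 44)
  spec <- movie_spec(width = 96, height = 96, fps = 2, duration_s = 15,
                     baseline_s = 5, pixel_noise_sd = 1e-4)
  mv <- generate_movie(atlas, "context_1", spec, seed = 5)
  zm <- zscore_movie(mv$movie, fps = spec$fps, onset_s = spec$baseline_s,
                     baseline_s = 5, pixel_um = spec$pixel_um)
  tbl <- quantify_rois(zm, mv$masks)
  planted <- mv$amplitudes[tbl$roi]
  active <- planted != 0
  expect_gt(sum(active), 2)
  # monotone recovery: stronger planted amplitude -> stronger measured z
  expect_gt(cor(planted[active], tbl$mean_z[active], method = "spearman"), 0.9)
  if (any(!active)) {
    expect_lt(max(tbl$mean_z[active]), min(tbl$mean_z[!active]))
  }
  # an all-zero atlas yields no detections at the regime threshold
  zero_spec <- atlas_spec(n_rois = 12,
                          frac_active = c(target = 0, contextual = 0,
                                          fixed = 0, novel = 0))
  mv0 <- generate_movie(generate_atlas(zero_spec, seed = 1), "context_1",
                        spec, seed = 6)
  zm0 <- zscore_movie(mv0$movie, fps = spec$fps, onset_s = spec$baseline_s,
                      baseline_s = 5, pixel_um = spec$pixel_um)
  tbl0 <- quantify_rois(zm0, mv0$masks)
  thresholded <- apply_detection_threshold(tbl0, -0.42)
  expect_true(all(thresholded$mean_z == 0))
})

test_that("TIFF stacks round-trip through disk", {
  arr <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  path <- tempfile(fileext = ".tif")
  write_tiff_stack(arr, path)
  back <- read_tiff_stack(path)
  expect_equal(back, arr, tolerance = 1e-6)
  unlink(path)
})
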