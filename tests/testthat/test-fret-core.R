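test_that("box smoothing matches hand convolution and preserves constants", {
  img <- matrix(3.5, 11, 13)
  expect_identical(smooth_image(img, 5L), img)
  expect_identical(smooth_image(img, 1L), img)
  # interior impulse of 25 spreads to a 5x5 patch of ones
  imp <- matrix(0, 11, 11)
  imp[6, 6] <- 25
  sm <- smooth_image(imp, 5L)
  expect_equal(sm[4:8, 4:8], matrix(1, 5, 5))
  expect_equal(sum(sm > 0), 25L)
  expect_error(smooth_image(imp, 4L), "odd")
})

test_that("box smoothing with replicated edges matches an independent filter", {
  set.seed(3)
  img <- matrix(rnorm(40 * 31, 100, 20), 40, 31)
  for (k in c(3L, 5L)) {
    ours <- smooth_image(img, k)
    ref <- EBImage::filter2(img, matrix(1 / k^2, k, k), boundary = "replicate")
    expect_equal(ours, ref, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("bleedthrough estimation is the ratio of background-subtracted means", {
  d <- matrix(runif(400, 50, 150), 20, 20)
  est <- estimate_bleedthrough(d, 0.15 * d)
  expect_equal(est$beta, 0.15, tolerance = 1e-12)
  expect_equal(est$n_pixels_used, 400L)
  # flat bleedthrough image at background level -> beta 0
  est0 <- estimate_bleedthrough(d + 10, matrix(20, 20, 20),
                                bg_donor = 10, bg_fret = 20)
  expect_equal(est0$beta, 0)
  expect_error(estimate_bleedthrough(matrix(1, 4, 4), matrix(1, 4, 4),
                                     bg_donor = 5), "not positive")
  expect_error(estimate_bleedthrough(d, d, mask = matrix(FALSE, 20, 20)),
               "no pixels")
})

test_that("noisy calibration recovers the generating beta within 3 SE", {
  spec <- scene_spec(height_px = 100L, width_px = 100L, n_frames = 1L,
                     beta = 0.15, bg_donor = 50, bg_fret = 80,
                     total_intensity = 1000, noise_sigma = 20, seed = 5L)
  pair <- render_calibration_pair(spec)
  est <- estimate_bleedthrough(pair$donor, pair$bleedthrough,
                               bg_donor = 50, bg_fret = 80)
  # SE of the ratio of means ~ sigma / (T * sqrt(n)) up to O(beta) terms
  se <- spec$noise_sigma / (spec$total_intensity * sqrt(1e4)) * sqrt(1 + 0.15^2)
  expect_lt(abs(est$beta - 0.15), 3 * se)
})

test_that("efficiency equals a straight per-pixel evaluation of the formulas", {
  set.seed(8)
  h <- 16L; w <- 16L
  eta_true <- matrix(runif(h * w, 0.3, 0.7), h, w)
  tot <- 500; beta <- 0.12; bgd <- 30; bgf <- 45
  d_raw <- bgd + (1 - eta_true) * tot
  f_raw <- bgf + eta_true * tot + beta * (1 - eta_true) * tot
  raw <- raw_timelapse(d_raw, f_raw)
  cfg <- correction_config(kernel_size = 1L, bg_donor = bgd, bg_fret = bgf,
                           beta = beta)
  eta <- compute_efficiency(raw, cfg)
  # independent re-implementation, straight from the two formulas
  i_d <- d_raw - bgd; i_f <- f_raw - bgf
  i_fret <- i_f - beta * i_d
  ref <- i_fret / (i_d + i_fret)
  expect_lt(max(abs(eta$eta[, , 1] - ref)), 1e-12)
  expect_true(all(eta$valid))
})

test_that("efficiency is invariant to rescaling both corrected channels", {
  set.seed(12)
  eta_true <- matrix(runif(64, 0.2, 0.8), 8, 8)
  mk <- function(scale) {
    d <- (1 - eta_true) * 200 * scale
    f <- eta_true * 200 * scale
    compute_efficiency(raw_timelapse(d, f),
                       correction_config(1L, 0, 0, beta = 0))$eta[, , 1]
  }
  expect_equal(mk(1), mk(7.3), tolerance = 1e-12)
})

test_that("validity flags partition pixels and are never silently zeroed", {
  # one pixel below the denominator floor, one negative corrected FRET
  d <- matrix(100, 4, 4); f <- matrix(150, 4, 4)
  d[1, 1] <- 0.2; f[1, 1] <- 0.3          # denominator ~0.5 < 1
  f[2, 2] <- 5                            # I_FRET = 5 - 0.2*100 < 0
  cfg <- correction_config(1L, 0, 0, beta = 0.2, min_denominator = 1)
  eta <- expect_silent(compute_efficiency(raw_timelapse(d, f), cfg))
  expect_false(eta$valid[1, 1, 1])
  expect_false(eta$valid[2, 2, 1])
  expect_true(is.na(eta$eta[1, 1, 1]) && is.na(eta$eta[2, 2, 1]))
  expect_equal(sum(eta$valid[, , 1]) + sum(!eta$valid[, , 1]), 16L)
  # eta = 0 (zero corrected FRET) is valid, not flagged
  f0 <- matrix(20, 4, 4)
  eta0 <- compute_efficiency(raw_timelapse(d, f0),
                             correction_config(1L, 0, 0, beta = 0.2))
  expect_equal(eta0$eta[4, 4, 1], 0)
  expect_true(eta0$valid[4, 4, 1])
  # an all-invalid frame warns but is kept
  expect_warning(
    compute_efficiency(raw_timelapse(matrix(0.1, 2, 2), matrix(0.1, 2, 2)),
                       correction_config(1L, 0, 0, beta = 0)),
    "no valid pixels")
})

test_that("background can come from a ROI of the first frame", {
  eta_true <- 0.45; tot <- 300; bgd <- 25; bgf <- 60
  d <- matrix(bgd + (1 - eta_true) * tot, 10, 10)
  f <- matrix(bgf + eta_true * tot, 10, 10)
  d[1:3, 1:3] <- bgd; f[1:3, 1:3] <- bgf    # signal-free corner
  roi <- matrix(FALSE, 10, 10); roi[1:3, 1:3] <- TRUE
  cfg <- correction_config(1L, bg_roi = roi, beta = 0)
  eta <- compute_efficiency(raw_timelapse(d, f), cfg)
  expect_equal(eta$eta[6, 6, 1], 0.45, tolerance = 1e-12)
  expect_error(correction_config(1L, beta = 0), "background")
})

test_that("floor calibration returns mean - 2 SD, with moment/histogram agreement", {
  expect_warning(fl <- calibrate_floor(rep(0.35, 200)), "degenerate")
  expect_equal(as.numeric(fl), 0.35)
  set.seed(2)
  x <- rnorm(2e4, 0.35, 0.034)
  fm <- calibrate_floor(x, method = "moments")
  fh <- calibrate_floor(x, method = "histogram")
  expect_equal(as.numeric(fm), mean(x) - 2 * sd(x), tolerance = 1e-12)
  expect_lt(abs(as.numeric(fh) - as.numeric(fm)) / abs(as.numeric(fm)), 0.01)
  expect_error(calibrate_floor(rnorm(50)), "at least 100")
})
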