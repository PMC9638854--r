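test_that("pouch labels have the constructed stripe geometry and exact areas", {
  spec <- scene_spec(height_px = 32L, width_px = 32L, pixel_size_um = 1,
                     n_frames = 2L)
  g <- list(ap_center_um = 15.5, ap_width_um = 8, dv_center_um = 15.5,
            dv_width_um = 8)
  lab <- build_pouch_labels(spec, g)
  # brute-force pixel count from the half-open band definition
  col_in <- which(abs((0:31) - 15.5) < 4 | (0:31) - 15.5 == -4)
  expect_length(col_in, 8L)
  expect_equal(sum(lab$masks$APB), 8 * 32)
  expect_equal(sum(lab$masks$DVB), 8 * 32)
  expect_equal(sum(lab$masks$ORG), 8 * 8)
  # stripe areas minus overlap counted once
  expect_equal(sum(lab$labels %in% c("APB", "DVB", "ORG")),
               8 * 32 + 8 * 32 - 8 * 8)
  # quadrants partition the remainder
  no_count <- sum(vapply(lab$masks[c("NO_DA", "NO_DP", "NO_VA", "NO_VP")],
                         sum, 1L))
  expect_equal(no_count, 32 * 32 - (8 * 32 + 8 * 32 - 8 * 8))
  expect_true(all(table(lab$labels) > 0))
  # every pixel has exactly one label
  expect_equal(length(lab$labels), 32 * 32)
})

test_that("degenerate or out-of-bounds stripe geometry is rejected by name", {
  spec <- scene_spec(height_px = 32L, width_px = 32L, pixel_size_um = 1,
                     n_frames = 2L)
  expect_error(build_pouch_labels(spec, list(ap_width_um = 0)), "AP stripe")
  expect_error(build_pouch_labels(spec, list(dv_width_um = -2)), "DV stripe")
  expect_error(build_pouch_labels(spec, list(ap_center_um = 2, ap_width_um = 10)),
               "AP stripe exceeds")
})

test_that("true_eta matches the logistic identities and the limit convention", {
  kin <- region_kinetics("r", base = 0.2827, max_eta = 0.7, t_half = 30,
                         hill = -2)
  expect_equal(true_eta(kin, 30), (0.2827 + 0.7) / 2)   # midpoint
  expect_equal(true_eta(kin, 60), 0.2827 + (0.7 - 0.2827) / 5,
               tolerance = 1e-12)                        # (30/60)^-2 = 4
  expect_equal(true_eta(kin, 0), 0.7)                    # continuous limit
  expect_error(region_kinetics("r", hill = 0), "nonzero")
  expect_error(true_eta(kin, -1), ">= 0")
})

test_that("decaying curves are non-increasing after drug addition", {
  set.seed(11)
  for (i in 1:20) {
    kin <- region_kinetics("r", base = 0.2827,
                           max_eta = runif(1, 0.4, 0.9),
                           t_half = runif(1, 5, 120),
                           hill = -runif(1, 0.5, 8))
    v <- true_eta(kin, seq(0, 180, by = 0.5))
    expect_true(all(diff(v) <= 1e-12))
    expect_true(all(v <= kin$max_eta + 1e-12 & v >= kin$base - 1e-12))
  }
})

test_that("render_frames inverts the efficiency formula exactly when noiseless", {
  # uniform one-region scene, hand-computed image formation
  spec <- scene_spec(height_px = 8L, width_px = 8L, pixel_size_um = 1,
                     n_frames = 1L, drug_time_min = 0, beta = 0,
                     bg_donor = 0, bg_fret = 0, total_intensity = 100,
                     noise_sigma = 0)
  lab <- build_pouch_labels(spec, list(ap_width_um = 4, dv_width_um = 4))
  same_kin <- lapply(setdiff(unique(as.vector(lab$labels)), "outside"),
                     function(l) region_kinetics(l, 0.2827, 0.6, 30, -2))
  truth <- scene_truth(lab, same_kin)
  raw <- render_frames(spec, truth)
  expect_true(all(raw$donor == 40))
  expect_true(all(raw$fret == 60))

  spec2 <- scene_spec(height_px = 8L, width_px = 8L, pixel_size_um = 1,
                      n_frames = 1L, drug_time_min = 0, beta = 0.1,
                      bg_donor = 5, bg_fret = 7, total_intensity = 100,
                      noise_sigma = 0)
  raw2 <- render_frames(spec2, truth)
  expect_true(all(raw2$donor == 45))
  expect_true(all(raw2$fret == 7 + 60 + 0.1 * 40))
})

test_that("noiseless rendering conserves the corrected total at every pixel", {
  sc <- tiny_scene(n_frames = 6L, noise_sigma = 0)
  raw <- render_frames(sc$spec, sc$truth)
  for (k in seq_len(6)) {
    d <- raw$donor[, , k] - sc$spec$bg_donor
    f <- raw$fret[, , k] - sc$spec$bg_fret
    tot <- (f - sc$spec$beta * d) + d
    expect_lt(max(abs(tot - sc$spec$total_intensity)), 1e-9)
  }
})

test_that("rendering is bit-identical under the same seed", {
  sc <- tiny_scene(n_frames = 3L, noise_sigma = 12, seed = 42L)
  r1 <- render_frames(sc$spec, sc$truth)
  r2 <- render_frames(sc$spec, sc$truth)
  expect_identical(r1$donor, r2$donor)
  expect_identical(r1$fret, r2$fret)
  sc2 <- tiny_scene(n_frames = 3L, noise_sigma = 12, seed = 43L)
  r3 <- render_frames(sc2$spec, sc2$truth)
  expect_false(identical(r1$donor, r3$donor))
})

test_that("pre-drug frames sit on the plateau", {
  sc <- tiny_scene(n_frames = 5L, noise_sigma = 0, drug_time_min = 2)
  raw <- render_frames(sc$spec, sc$truth)
  # frames at t = 0, 1, 2 are all pre/at drug: identical plateau frames
  expect_identical(raw$fret[, , 1], raw$fret[, , 2])
  expect_identical(raw$fret[, , 2], raw$fret[, , 3])
  expect_false(identical(raw$fret[, , 3], raw$fret[, , 4]))
})

test_that("calibration pair encodes the bleedthrough fraction", {
  spec <- scene_spec(height_px = 16L, width_px = 16L, n_frames = 1L,
                     beta = 0.15, bg_donor = 0, bg_fret = 0,
                     total_intensity = 200, noise_sigma = 0)
  pair <- render_calibration_pair(spec)
  expect_true(all(abs(pair$bleedthrough / pair$donor - 0.15) < 1e-12))
  spec0 <- scene_spec(height_px = 16L, width_px = 16L, n_frames = 1L,
                      beta = 0, bg_donor = 10, bg_fret = 30,
                      total_intensity = 200, noise_sigma = 0)
  pair0 <- render_calibration_pair(spec0)
  expect_true(all(pair0$bleedthrough == 30))
})

test_that("simulate_cohort_traces reproduces the 4PL grid plus seeded noise", {
  kin <- region_kinetics("r", 0.2827, 0.6, 30, -2.3)
  tr <- simulate_cohort_traces(list(kin), n_discs = 2, n_frames = 20,
                               drug_time_min = 5, noise_sigma = 0, seed = 1)
  expect_equal(nrow(tr), 40L)
  post <- tr[tr$disc_id == "disc01" & tr$time_min > 5, ]
  expect_equal(post$mean_eta, true_eta(kin, post$time_min - 5))
  pre <- tr[tr$time_min <= 5, ]
  expect_true(all(pre$mean_eta == 0.6))
  tr2 <- simulate_cohort_traces(list(kin), n_discs = 2, n_frames = 20,
                                drug_time_min = 5, noise_sigma = 0.01, seed = 9)
  tr3 <- simulate_cohort_traces(list(kin), n_discs = 2, n_frames = 20,
                                drug_time_min = 5, noise_sigma = 0.01, seed = 9)
  expect_identical(tr2$mean_eta, tr3$mean_eta)
})
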