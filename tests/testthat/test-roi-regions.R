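test_that("scheme geometry: 9 circles, 5 distinct organizer centres, hand-checked", {
  sch <- make_roi_scheme(intersection = c(128, 128), ap_dir = c(1, 0),
                         dv_dir = c(0, 1), spacing_um = 30, diameter_um = 20,
                         pixel_size_um = 1, image_shape = c(256, 256))
  expect_equal(nrow(sch$circles), 9L)
  ap <- sch$circles[sch$circles$role %in% c("AP1", "C", "AP2"), c("row", "col")]
  expect_setequal(ap$row, c(98, 128, 158))
  expect_true(all(ap$col == 128))
  dv <- sch$circles[sch$circles$role %in% c("DV1", "DV2"), c("row", "col")]
  expect_setequal(dv$col, c(98, 158))
  org <- sch$circles[sch$circles$role %in% sch$members$ORG, ]
  expect_equal(nrow(unique(org[, c("row", "col")])), 5L)
  no <- sch$circles[grepl("^NO", sch$circles$role), ]
  # quadrant midpoints between the intersection and the image corners
  expect_setequal(paste(no$row, no$col),
                  c("64 64", "64 191.5", "191.5 64", "191.5 191.5"))
  expect_error(make_roi_scheme(c(128, 128), spacing_um = 0, pixel_size_um = 1,
                               image_shape = c(256, 256)), "spacing_um")
  expect_error(make_roi_scheme(c(128, 128), ap_dir = c(1, 0), dv_dir = c(2, 0),
                               pixel_size_um = 1, image_shape = c(256, 256)),
               "parallel")
  expect_error(make_roi_scheme(c(5, 128), pixel_size_um = 1,
                               image_shape = c(256, 256)), "out of image bounds")
})

test_that("circle rasterization is inclusive of the radius and symmetric", {
  m <- circle_mask(c(10, 10), 3, c(21, 21))
  expect_true(m[10 + 1, 13 + 1])                 # on-radius pixel included
  expect_false(m[10 + 1, 14 + 1])
  expect_identical(m, t(m))                      # symmetric about the centre
  expect_equal(sum(m), sum(circle_mask(c(7, 13), 3, c(21, 21))))
})

test_that("uniform stacks give constant traces for every region type", {
  eta <- uniform_eta_stack(0.5)
  sch <- make_roi_scheme(c(31.5, 31.5), spacing_um = 15, diameter_um = 10,
                         pixel_size_um = 1, image_shape = c(64, 64))
  tr <- roi_traces(eta, sch)
  expect_true(all(tr$mean_eta == 0.5))
  expect_setequal(unique(tr$region), c("APB", "DVB", "ORG", "NO"))
  sq <- function(r0, r1, c0, c1) {
    cbind(c(r0, r0, r1, r1), c(c0, c1, c1, c0))
  }
  sch$dorsal_polygon <- sq(-0.5, 31.4, -0.5, 63.5)
  sch$ventral_polygon <- sq(31.6, 63.5, -0.5, 63.5)
  ct <- compartment_traces(eta, sch)
  expect_setequal(unique(ct$region), c("D", "V", "DA", "DP", "VA", "VP"))
  expect_true(all(ct$mean_eta == 0.5))
})

test_that("composite regions use ROI-mean-of-means, not pixel pooling", {
  # gradient image: the two aggregations differ measurably
  d <- c(32L, 32L, 1L)
  grad <- matrix(rep(seq(0, 1, length.out = 32), each = 32), 32, 32)
  eta <- uniform_eta_stack(0, shape = c(32L, 32L), n_frames = 1L)
  eta$eta <- array(grad, d)
  m1 <- circle_mask(c(16, 6), 5, c(32, 32))   # 121 px
  m2 <- circle_mask(c(16, 25), 3, c(32, 32))  #  45 px
  tr <- extract_trace(eta, list(a = m1, b = m2), label = "comp")
  mean_of_means <- mean(c(mean(grad[m1]), mean(grad[m2])))
  pooled <- mean(grad[m1 | m2])
  expect_equal(tr$mean_eta, mean_of_means, tolerance = 1e-12)
  expect_gt(abs(mean_of_means - pooled), 1e-3)
  expect_equal(tr$n_valid, sum(m1) + sum(m2))
  # for equal-area circles on a uniform image the two aggregations agree
  eta_u <- uniform_eta_stack(0.4, shape = c(32L, 32L), n_frames = 1L)
  m3 <- circle_mask(c(10, 10), 4, c(32, 32))
  m4 <- circle_mask(c(22, 22), 4, c(32, 32))
  tru <- extract_trace(eta_u, list(m3, m4))
  expect_equal(tru$mean_eta, 0.4)
})

test_that("trace extraction respects validity and rejects empty regions", {
  eta <- uniform_eta_stack(0.5, shape = c(16L, 16L), n_frames = 3L)
  eta$eta[, , 2] <- NA; eta$valid[, , 2] <- FALSE
  m <- circle_mask(c(8, 8), 4, c(16, 16))
  tr <- extract_trace(eta, m)
  expect_true(is.na(tr$mean_eta[2]))
  expect_equal(tr$n_valid[2], 0L)
  expect_equal(tr$mean_eta[c(1, 3)], c(0.5, 0.5))
  expect_error(extract_trace(eta, matrix(FALSE, 16, 16)), "empty region")
  all_na <- uniform_eta_stack(0.5, shape = c(16L, 16L), n_frames = 2L)
  all_na$eta[] <- NA
  expect_error(extract_trace(all_na, m), "no valid pixels")
})

test_that("traces are invariant to padding that does not touch the regions", {
  sc <- tiny_scene(n_frames = 6L, noise_sigma = 0)
  raw <- render_frames(sc$spec, sc$truth)
  cfg <- correction_config(1L, sc$spec$bg_donor, sc$spec$bg_fret,
                           beta = sc$spec$beta)
  eta <- compute_efficiency(raw, cfg)
  m <- circle_mask(c(31.5, 31.5), 5, c(64, 64))
  tr <- extract_trace(eta, m)
  pad <- function(a, n) {
    out <- array(0, dim(a) + c(n, n, 0))
    out[seq_len(dim(a)[1]), seq_len(dim(a)[2]), ] <- a
    out
  }
  raw_p <- raw_timelapse(pad(raw$donor, 8), pad(raw$fret, 8),
                         frame_interval_min = raw$frame_interval_min,
                         drug_time_min = raw$drug_time_min)
  eta_p <- suppressWarnings(compute_efficiency(raw_p, cfg))
  m_p <- rbind(cbind(m, matrix(FALSE, 64, 8)), matrix(FALSE, 8, 72))
  tr_p <- extract_trace(eta_p, m_p)
  expect_equal(tr_p$mean_eta, tr$mean_eta, tolerance = 1e-12)
})

test_that("compartment splits partition the pouch and order by kinetics", {
  sc <- tiny_scene(n_frames = 10L, noise_sigma = 0, drug_time_min = 2)
  raw <- render_frames(sc$spec, sc$truth)
  eta <- compute_efficiency(
    raw, correction_config(1L, sc$spec$bg_donor, sc$spec$bg_fret,
                           beta = sc$spec$beta))
  sch <- tiny_scheme(sc$labels)
  sq <- function(r0, r1, c0, c1) cbind(c(r0, r0, r1, r1), c(c0, c1, c1, c0))
  sch$dorsal_polygon <- sq(-0.5, 31.4, -0.5, 63.5)
  sch$ventral_polygon <- sq(31.6, 63.5, -0.5, 63.5)
  ct <- compartment_traces(eta, sch)
  # D and V tile the pouch; DA and DP tile D, disjointly
  d <- fretkin:::polygon_mask(sch$dorsal_polygon, c(64, 64))
  v <- fretkin:::polygon_mask(sch$ventral_polygon, c(64, 64))
  expect_equal(sum(d) + sum(v), 64 * 64)
  expect_equal(sum(d & v), 0L)
  da <- ct[ct$region == "DA", ]; dp <- ct[ct$region == "DP", ]
  dd <- ct[ct$region == "D", ]
  expect_equal(da$n_valid + dp$n_valid, dd$n_valid)
  # organizer (slower, t_half 45) stays above non-organizer (30) post drug
  tro <- roi_traces(eta, sch, c("APB", "NO"))
  apb <- tro$mean_eta[tro$region == "APB" & tro$time_min > 2]
  no <- tro$mean_eta[tro$region == "NO" & tro$time_min > 2]
  expect_true(all(apb >= no))
})

test_that("noiseless scene traces match the generating curves (eroded regions)", {
  sc <- tiny_scene(n_frames = 10L, noise_sigma = 0, drug_time_min = 2)
  raw <- render_frames(sc$spec, sc$truth)
  eta <- compute_efficiency(
    raw, correction_config(1L, sc$spec$bg_donor, sc$spec$bg_fret,
                           beta = sc$spec$beta))
  sch <- tiny_scheme(sc$labels)
  tr <- roi_traces(eta, sch, c("APB", "NO"))
  kin_org <- sc$kinetics[[1]]; kin_no <- sc$kinetics[[4]]
  for (k in which(tr$time_min > 2 & tr$region == "APB")) {
    expect_equal(tr$mean_eta[k],
                 true_eta(kin_org, tr$time_min[k] - 2), tolerance = 1e-9)
  }
  for (k in which(tr$time_min > 2 & tr$region == "NO")) {
    expect_equal(tr$mean_eta[k],
                 true_eta(kin_no, tr$time_min[k] - 2), tolerance = 1e-9)
  }
})

test_that("landmark JSON round-trips a scheme", {
  sch <- make_roi_scheme(c(31.5, 31.5), spacing_um = 15, diameter_um = 10,
                         pixel_size_um = 1, image_shape = c(64, 64),
                         dorsal_polygon = cbind(c(0, 0, 31, 31), c(0, 63, 63, 0)),
                         ventral_polygon = cbind(c(32, 32, 63, 63), c(0, 63, 63, 0)),
                         anterior_point = c(31, 5))
  path <- withr::local_tempfile(fileext = ".json")
  write_landmarks(sch, path)
  sch2 <- read_landmarks(path)
  expect_equal(sch2$circles, sch$circles, tolerance = 1e-12)
  expect_equal(sch2$dorsal_polygon, sch$dorsal_polygon, ignore_attr = TRUE)
  expect_equal(sch2$anterior_point, sch$anterior_point)
})
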