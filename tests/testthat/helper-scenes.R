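# Shared fixtures: small scenes and independent oracles, built in code.

# A compact two-region scene (organizer 45 min vs non-organizer 30 min,
# hill -2.3) on a 64 x 64 px, 1 um/px grid. Stripes 16 um so the geometry
# fits; ROI scheme shrunk to match.
tiny_scene <- function(n_frames = 12L, noise_sigma = 0, seed = 7L,
                       drug_time_min = 2) {
  spec <- scene_spec(height_px = 64L, width_px = 64L, pixel_size_um = 1,
                     n_frames = n_frames, frame_interval_min = 1,
                     drug_time_min = drug_time_min, beta = 0.12,
                     bg_donor = 50, bg_fret = 80, total_intensity = 1000,
                     noise_sigma = noise_sigma, seed = seed)
  geometry <- list(ap_width_um = 16, dv_width_um = 16)
  kin <- c(lapply(c("APB", "DVB", "ORG"),
                  function(l) region_kinetics(l, 0.2827, 0.6, 45, -2.3)),
           lapply(c("NO_DA", "NO_DP", "NO_VA", "NO_VP"),
                  function(l) region_kinetics(l, 0.2827, 0.6, 30, -2.3)))
  labels <- build_pouch_labels(spec, geometry)
  list(spec = spec, geometry = geometry, kinetics = kin,
       labels = labels, truth = scene_truth(labels, kin))
}

tiny_scheme <- function(labels, diameter_um = 10, spacing_um = 15) {
  g <- labels$geometry
  make_roi_scheme(
    intersection = c(g$dv_center_um, g$ap_center_um) / labels$pixel_size_um,
    spacing_um = spacing_um, diameter_um = diameter_um,
    pixel_size_um = labels$pixel_size_um,
    image_shape = c(labels$height_px, labels$width_px))
}

# Uniform-efficiency stack (no region structure), for aggregation identities.
uniform_eta_stack <- function(eta0 = 0.5, shape = c(64L, 64L), n_frames = 5L,
                              drug_time_min = 0) {
  d <- c(shape, n_frames)
  structure(list(eta = array(eta0, d), valid = array(TRUE, d),
                 times_min = seq_len(n_frames) - 1,
                 drug_time_min = drug_time_min, pixel_size_um = 1,
                 backgrounds = c(donor = 0, fret = 0), beta = 0,
                 kernel_size = 1L),
            class = "efficiency_stack")
}

# --- independent oracles -------------------------------------------------

# Rank-formula Kruskal-Wallis H (tie-corrected), written from the textbook
# definition, independent of stats::kruskal.test.
oracle_kw_h <- function(groups) {
  x <- unlist(groups)
  n <- length(x)
  r <- rank(x)
  ri <- split(r, rep(seq_along(groups), vapply(groups, length, 1L)))
  h <- 12 / (n * (n + 1)) *
    sum(vapply(ri, function(z) sum(z)^2 / length(z), 1)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Exhaustive permutation p-value for any statistic on a two-group split.
oracle_perm_p <- function(a, b, stat) {
  x <- c(a, b)
  idx <- utils::combn(length(x), length(a))
  obs <- stat(a, b)
  ps <- apply(idx, 2, function(i) stat(x[i], x[-i]))
  mean(ps >= obs - 1e-12)
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
oracle_mw_exact <- function(a, b) {
  u_stat <- function(g1, g2) sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
  x <- c(a, b)
  idx <- utils::combn(length(x), length(a))
  m <- length(a) * length(b)
  obs <- abs(u_stat(a, b) - m / 2)
  us <- apply(idx, 2, function(i) abs(u_stat(x[i], x[-i]) - m / 2))
  mean(us >= obs - 1e-12)
}
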