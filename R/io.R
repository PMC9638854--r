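# File formats and the end-to-end pipeline.
#
# Interchange formats: multi-page TIFF for image stacks (page order T x C,
# channel 0 = donor, channel 1 = FRET; raw stacks stored as 16-bit unsigned
# integer ADU — camera counts are integers — efficiency maps as 32-bit
# float with NaN marking invalid pixels), CSV for traces and fits, TSV for
# comparisons, JSON for configurations and landmarks.

TIFF_MAX <- 65535

#' Write a raw two-channel time-lapse as a multi-page TIFF
#'
#' Pages are ordered frame-major (donor, FRET, donor, FRET, ...). Values
#' are stored as 16-bit unsigned integers, so they must lie in
#' `[0, 65535]`; non-integer values are rounded (real acquisitions are
#' integer ADU already).
#'
#' @param raw A [raw_timelapse()].
#' @param path Output TIFF path.
#' @export
write_stack <- function(raw, path) {
  stopifnot(inherits(raw, "raw_timelapse"))
  rng <- range(raw$donor, raw$fret)
  if (rng[1] < 0 || rng[2] > TIFF_MAX) {
    stop("stack values outside [0, 65535]; 16-bit storage would clip",
         call. = FALSE)
  }
  tt <- dim(raw$donor)[3]
  pages <- vector("list", 2L * tt)
  for (k in seq_len(tt)) {
    pages[[2L * k - 1L]] <- raw$donor[, , k] / TIFF_MAX
    pages[[2L * k]] <- raw$fret[, , k] / TIFF_MAX
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' Read a two-channel time-lapse TIFF
#'
#' @param path TIFF path written as frame-major (`"TC"`, default) or
#'   channel-major (`"CT"`) pages; declare which.
#' @param axis_order `"TC"` (donor/FRET alternating per frame) or `"CT"`
#'   (all donor frames then all FRET frames).
#' @param pixel_size_um,frame_interval_min,drug_time_min Acquisition
#'   metadata (config values override any file tags).
#' @return A [raw_timelapse()] with integer ADU values.
#' @export
read_stack <- function(path, axis_order = c("TC", "CT"), pixel_size_um = 0.22,
                       frame_interval_min = 1, drug_time_min = 0) {
  axis_order <- match.arg(axis_order)
  pages <- tiff::readTIFF(path, all = TRUE)
  n <- length(pages)
  if (n < 2L || n %% 2L != 0L) {
    stop("expected an even number of pages (two channels); got ", n,
         call. = FALSE)
  }
  tt <- n %/% 2L
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  donor <- array(0, c(h, w, tt)); fret <- array(0, c(h, w, tt))
  for (k in seq_len(tt)) {
    if (axis_order == "TC") {
      donor[, , k] <- pages[[2L * k - 1L]]
      fret[, , k] <- pages[[2L * k]]
    } else {
      donor[, , k] <- pages[[k]]
      fret[, , k] <- pages[[tt + k]]
    }
  }
  raw_timelapse(round(donor * TIFF_MAX), round(fret * TIFF_MAX),
                pixel_size_um = pixel_size_um,
                frame_interval_min = frame_interval_min,
                drug_time_min = drug_time_min)
}

#' Write an efficiency stack as a 32-bit float TIFF (NaN = invalid)
#'
#' @param eta An `efficiency_stack`.
#' @param path Output TIFF path.
#' @export
write_eta_stack <- function(eta, path) {
  stopifnot(inherits(eta, "efficiency_stack"))
  tt <- dim(eta$eta)[3]
  pages <- lapply(seq_len(tt), function(k) {
    m <- eta$eta[, , k]
    m[is.na(m)] <- NaN
    m
  })
  suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                                   reduce = FALSE))
  invisible(path)
}

#' Write / read region traces as CSV
#'
#' Columns: `disc_id`, `region`, `frame`, `time_min`, `mean_eta`,
#' `n_valid`; the drug-addition time rides along as a commented header
#' line.
#'
#' @param traces Trace data frame.
#' @param path CSV path.
#' @export
write_traces <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# drug_time_min=%g", attr(traces, "drug_time_min")), con)
  utils::write.csv(traces, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  first <- readLines(path, n = 1L)
  drug <- if (grepl("^# drug_time_min=", first)) {
    as.numeric(sub("^# drug_time_min=", "", first))
  } else {
    NULL
  }
  out <- utils::read.csv(path, comment.char = "#")
  attr(out, "drug_time_min") <- drug
  out
}

#' Write a fit table as CSV
#'
#' @param fits A [fit_cohort()] data frame.
#' @param path CSV path.
#' @export
write_fits <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE)
  invisible(path)
}

#' Serialise / load a scene configuration
#'
#' JSON with the [scene_spec()] fields, a region-kinetics table and the
#' stripe geometry.
#'
#' @param spec A [scene_spec()].
#' @param kinetics List of [region_kinetics()].
#' @param geometry Stripe geometry list (see [build_pouch_labels()]).
#' @param path JSON path.
#' @export
write_scene_config <- function(spec, kinetics, geometry = list(), path) {
  stopifnot(inherits(spec, "scene_spec"))
  kin <- do.call(rbind, lapply(kinetics, function(k) {
    data.frame(label = k$label, base = k$base, max_eta = k$max_eta,
               t_half = k$t_half, hill = k$hill)
  }))
  jsonlite::write_json(list(scene = unclass(spec), kinetics = kin,
                            geometry = geometry),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(scene_spec, cfg$scene[setdiff(names(cfg$scene), character(0))])
  kin <- lapply(seq_len(nrow(cfg$kinetics)), function(i) {
    with(cfg$kinetics[i, ], region_kinetics(label, base, max_eta, t_half, hill))
  })
  list(spec = spec, kinetics = kin,
       geometry = as.list(cfg$geometry))
}

#' Ground-truth CSV of a scene (region, base, max, t_half, hill)
#'
#' @param truth A [scene_truth()].
#' @param path CSV path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "scene_truth"))
  df <- do.call(rbind, lapply(truth$kinetics, function(k) {
    data.frame(region = k$label, base = k$base, max_eta = k$max_eta,
               t_half = k$t_half, hill = k$hill)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

default_scheme_for_labels <- function(labels) {
  g <- labels$geometry; px <- labels$pixel_size_um
  make_roi_scheme(
    intersection = c(g$dv_center_um, g$ap_center_um) / px,
    spacing_um = 1.5 * 20,
    diameter_um = min(20, g$ap_width_um, g$dv_width_um),
    pixel_size_um = px,
    image_shape = c(labels$height_px, labels$width_px))
}

pipeline_log <- function(con, stage, ...) {
  line <- sprintf("[%s] %s", stage, sprintf(...))
  writeLines(line, con)
  message(line)
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Composes all stages: render a two-channel scene per virtual disc,
#' estimate the bleedthrough fraction from a rendered donor-only
#' calibration pair, compute per-pixel efficiency, extract organizer /
#' non-organizer ROI traces, fit the constrained 4PL per disc and region,
#' and compare a fit parameter between regions. Deterministic for a given
#' seed; every output embeds the configuration hash and package version.
#'
#' @param config List with elements `scene` (a [scene_spec()]; its `seed`
#'   is re-derived per disc), `kinetics` (list of [region_kinetics()] for
#'   the pouch labels), `geometry` (stripe geometry), `n_discs`,
#'   `correction` (partial [correction_config()] overrides), `fit`
#'   (a [fit_config()]), `comparison` (list: `regions`, `param`, `test`),
#'   `seed`, `out_dir`.
#' @return Invisibly, list with `traces`, `fits`, `comparison`, and the
#'   output paths (`traces.csv`, `fits.csv`, `comparison.tsv`,
#'   `pipeline.log` under `out_dir`).
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(list(
    n_discs = 8L, seed = 1L, out_dir = tempfile("fretkin_run_"),
    geometry = list(),
    correction = list(),
    fit = fit_config(),
    comparison = list(regions = c("ORG", "NO"), param = "t_half",
                      test = "kruskal")
  ), config)
  if (is.null(cfg$scene)) stop("config needs a `scene`", call. = FALSE)
  if (is.null(cfg$kinetics)) stop("config needs `kinetics`", call. = FALSE)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  con <- file(log_path, "w")
  on.exit(close(con))
  cfg_hash <- rlang::hash(cfg[c("scene", "kinetics", "geometry", "n_discs",
                                "correction", "fit", "comparison", "seed")])
  ver <- as.character(utils::packageVersion("fretkin"))
  pipeline_log(con, "config", "hash=%s fretkin=%s seed=%d discs=%d",
               cfg_hash, ver, cfg$seed, cfg$n_discs)

  labels <- build_pouch_labels(cfg$scene, cfg$geometry)
  truth <- scene_truth(labels, cfg$kinetics)
  scheme <- if (!is.null(cfg$scheme)) cfg$scheme else default_scheme_for_labels(labels)

  cal_spec <- cfg$scene
  cal_spec$seed <- derive_seed(cfg$seed, 0L)
  pair <- render_calibration_pair(cal_spec)
  bt <- estimate_bleedthrough(pair$donor, pair$bleedthrough,
                              bg_donor = cal_spec$bg_donor,
                              bg_fret = cal_spec$bg_fret)
  pipeline_log(con, "bleedthrough", "beta=%.5f n=%d (true %.5f)",
               bt$beta, bt$n_pixels_used, cfg$scene$beta)

  corr <- do.call(correction_config, utils::modifyList(
    list(kernel_size = 5L, bg_donor = cfg$scene$bg_donor,
         bg_fret = cfg$scene$bg_fret, beta = bt$beta),
    cfg$correction))

  traces <- do.call(rbind, lapply(seq_len(cfg$n_discs), function(d) {
    spec_d <- cfg$scene
    spec_d$seed <- derive_seed(cfg$seed, d)
    raw <- render_frames(spec_d, truth)
    eta <- compute_efficiency(raw, corr)
    tr <- roi_traces(eta, scheme, regions = cfg$comparison$regions,
                     disc_id = sprintf("disc%02d", d))
    pipeline_log(con, "disc", "%s frames=%d valid=%.1f%%",
                 sprintf("disc%02d", d), dim(eta$eta)[3], 100 * mean(eta$valid))
    tr
  }))
  attr(traces, "drug_time_min") <- cfg$scene$drug_time_min
  pipeline_log(con, "traces", "regions=%s rows=%d",
               paste(cfg$comparison$regions, collapse = ","), nrow(traces))

  fits <- fit_cohort(traces, cfg$fit, drug_time_min = cfg$scene$drug_time_min)
  pipeline_log(con, "fits", "converged=%d/%d",
               sum(fits$converged[fits$level == "disc"]),
               sum(fits$level == "disc"))

  comparison <- compare_fits(fits, cfg$comparison$regions,
                             cfg$comparison$param, cfg$comparison$test)
  if (!is.null(comparison$p_value)) {
    pipeline_log(con, "compare", "%s on %s: p=%.4g",
                 comparison$method, cfg$comparison$param, comparison$p_value)
  }

  traces_path <- file.path(cfg$out_dir, "traces.csv")
  fits_path <- file.path(cfg$out_dir, "fits.csv")
  cmp_path <- file.path(cfg$out_dir, "comparison.tsv")
  write_traces(traces, traces_path)
  write_fits(cbind(fits, config_hash = cfg_hash, fretkin_version = ver),
             fits_path)
  cmp_df <- data.frame(
    param = comparison$param,
    regions = paste(comparison$regions, collapse = ","),
    method = if (is.null(comparison$method)) "estimation" else comparison$method,
    statistic = if (is.null(comparison$statistic)) NA else comparison$statistic,
    p_value = if (is.null(comparison$p_value)) NA else comparison$p_value,
    config_hash = cfg_hash, fretkin_version = ver)
  utils::write.table(cmp_df, cmp_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(list(traces = traces, fits = fits, comparison = comparison,
                 beta = bt, paths = list(traces = traces_path,
                                         fits = fits_path,
                                         comparison = cmp_path,
                                         log = log_path)))
}
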