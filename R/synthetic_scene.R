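# Synthetic two-channel time-lapse generator.
#
# Renders a virtual wing-disc pouch whose regions lose FRET efficiency by
# four-parameter-logistic kinetics, by inverting the analysis formulas:
# given a true efficiency eta and a total corrected intensity T per pixel,
# the corrected channels are I_D = (1 - eta) * T and I_FRET = eta * T, and
# the raw channels add background, donor bleedthrough and Gaussian noise.
# Every rendered scene carries its ground truth, so the analysis pipeline
# can be validated end to end by round trip and parameter recovery.

#' Specify a synthetic imaging scene
#'
#' Collects the geometry, timing and image-formation parameters of a virtual
#' two-channel (donor, FRET) time-lapse. Defaults emulate a 2-h acquisition at
#' 1 frame/min with drug addition at 10 min, on a 60x/EMCCD-like sampling of
#' 0.22 um/px.
#'
#' @param height_px,width_px Image size in pixels.
#' @param pixel_size_um Pixel size in micrometres.
#' @param n_frames Number of frames.
#' @param frame_interval_min Time between frames, minutes.
#' @param drug_time_min Time of drug addition relative to frame 0, minutes.
#'   Frames acquired at or before this time show the pre-drug plateau.
#' @param beta Donor-to-FRET-channel bleedthrough fraction, in `[0, 1)`.
#' @param bg_donor,bg_fret Additive channel backgrounds (ADU).
#' @param total_intensity Expected corrected summed intensity per pixel
#'   `T = I_D + I_FRET` (ADU).
#' @param noise_sigma SD of the additive Gaussian pixel noise per channel (ADU).
#' @param noise_model Noise model tag; only `"gaussian"` is implemented. The
#'   field exists so other models can be added without changing the contract.
#' @param seed Integer RNG seed used by the renderers.
#' @return A `scene_spec` object (a validated list of the above fields).
#' @examples
#' spec <- scene_spec(height_px = 64, width_px = 64, n_frames = 20)
#' @export
scene_spec <- function(height_px = 128L, width_px = 128L,
                       pixel_size_um = 0.22,
                       n_frames = 130L, frame_interval_min = 1,
                       drug_time_min = 10,
                       beta = 0.15, bg_donor = 100, bg_fret = 120,
                       total_intensity = 2000, noise_sigma = 10,
                       noise_model = "gaussian", seed = 1L) {
  stopifnot_scalar(height_px, "height_px", positive = TRUE)
  stopifnot_scalar(width_px, "width_px", positive = TRUE)
  stopifnot_scalar(pixel_size_um, "pixel_size_um", positive = TRUE)
  stopifnot_scalar(n_frames, "n_frames", positive = TRUE)
  stopifnot_scalar(frame_interval_min, "frame_interval_min", positive = TRUE)
  stopifnot_scalar(drug_time_min, "drug_time_min", nonneg = TRUE)
  stopifnot_scalar(beta, "beta", nonneg = TRUE)
  if (beta >= 1) stop("`beta` must be < 1", call. = FALSE)
  stopifnot_scalar(total_intensity, "total_intensity", positive = TRUE)
  stopifnot_scalar(noise_sigma, "noise_sigma", nonneg = TRUE)
  noise_model <- match.arg(noise_model, "gaussian")
  structure(list(
    height_px = as.integer(height_px), width_px = as.integer(width_px),
    pixel_size_um = pixel_size_um, n_frames = as.integer(n_frames),
    frame_interval_min = frame_interval_min, drug_time_min = drug_time_min,
    beta = beta, bg_donor = bg_donor, bg_fret = bg_fret,
    total_intensity = total_intensity, noise_sigma = noise_sigma,
    noise_model = noise_model, seed = as.integer(seed)
  ), class = "scene_spec")
}

#' Four-parameter-logistic kinetics of one region
#'
#' Bundles the decay parameters of one named region: the sensor floor `base`,
#' the pre-drug plateau `max_eta`, the half-life `t_half` (minutes) and the
#' Hill coefficient `hill` (negative for a decline).
#'
#' @param label Region name.
#' @param base Lower efficiency asymptote, in `(0, max_eta)`.
#' @param max_eta Upper efficiency asymptote, in `(base, 1]`.
#' @param t_half Half-life in minutes (> 0).
#' @param hill Hill coefficient; negative values decay from `max_eta` to
#'   `base`. Zero is rejected (degenerate curve).
#' @return A `region_kinetics` object.
#' @export
region_kinetics <- function(label, base = 0.2827, max_eta = 0.6,
                            t_half = 30, hill = -2.3) {
  stopifnot(is.character(label), length(label) == 1L)
  stopifnot_scalar(base, "base", positive = TRUE)
  stopifnot_scalar(max_eta, "max_eta", positive = TRUE)
  stopifnot_scalar(t_half, "t_half", positive = TRUE)
  stopifnot_scalar(hill, "hill")
  if (hill == 0) stop("`hill` must be nonzero (hill = 0 is a flat, degenerate curve)",
                      call. = FALSE)
  if (!(base < max_eta && max_eta <= 1)) {
    stop("require 0 < base < max_eta <= 1", call. = FALSE)
  }
  structure(list(label = label, base = base, max_eta = max_eta,
                 t_half = t_half, hill = hill),
            class = "region_kinetics")
}

#' True efficiency of a region at a time since drug addition
#'
#' Evaluates the region's four-parameter logistic at `t_min` minutes after
#' drug addition. At `t_min = 0` the continuous limit is used, which for a
#' decaying curve (`hill < 0`) equals `max_eta`; callers use `eta = max_eta`
#' for all pre-drug frames.
#'
#' @param kin A [region_kinetics()] object.
#' @param t_min Minutes since drug addition (vectorised, all >= 0).
#' @return Efficiency values, same length as `t_min`.
#' @export
true_eta <- function(kin, t_min) {
  stopifnot(inherits(kin, "region_kinetics"))
  if (any(t_min < 0)) stop("`t_min` must be >= 0", call. = FALSE)
  four_pl(t_min, kin$base, kin$max_eta, kin$t_half, kin$hill)
}

#' Label the regions of a rectangular virtual pouch
#'
#' Builds a per-pixel label image with a vertical stripe just anterior of the
#' anterior-posterior (AP) compartment line and a horizontal stripe on the
#' dorsal-ventral (DV) line; their intersection is the organizer. The four
#' quadrants outside the stripes are the non-organizer sub-compartments
#' (dorsal/ventral x anterior/posterior). Real pouches are curved; a
#' rectangle with axis-aligned stripes is used because geometry only enters
#' through region membership, never through any formula.
#'
#' Pixel `(i, j)` (0-based row, col) sits at `(i, j) * pixel_size_um`;
#' a stripe of centre `c` and width `w` (um) contains coordinates in the
#' half-open band `[c - w/2, c + w/2)`, so aligned stripes have exactly
#' `w / pixel_size` pixels across.
#'
#' @param spec A [scene_spec()].
#' @param geometry List with `ap_center_um`, `ap_width_um` (vertical stripe:
#'   column position/width), `dv_center_um`, `dv_width_um` (horizontal
#'   stripe: row position/width), and optional `margin_um` (border labelled
#'   `outside`). Defaults: stripes of 20 um at the image midlines, no margin.
#' @return A `pouch_labels` object: `$labels` (character matrix with levels
#'   `APB`, `DVB`, `ORG`, `NO_DA`, `NO_DP`, `NO_VA`, `NO_VP`, `outside`) and
#'   `$masks`, a named list of logical matrices. `masks$APB` / `masks$DVB`
#'   are the full stripes including the organizer overlap, so membership in
#'   both is recorded; the label matrix shows `ORG` at the overlap.
#' @export
build_pouch_labels <- function(spec, geometry = list()) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height_px; w <- spec$width_px; px <- spec$pixel_size_um
  g <- utils::modifyList(list(
    ap_center_um = (w - 1) / 2 * px, ap_width_um = 20,
    dv_center_um = (h - 1) / 2 * px, dv_width_um = 20,
    margin_um = 0
  ), geometry)
  if (g$ap_width_um <= 0) stop("AP stripe width must be > 0", call. = FALSE)
  if (g$dv_width_um <= 0) stop("DV stripe width must be > 0", call. = FALSE)
  row_um <- (seq_len(h) - 1) * px
  col_um <- (seq_len(w) - 1) * px
  if (g$ap_center_um - g$ap_width_um / 2 < 0 ||
      g$ap_center_um + g$ap_width_um / 2 > (w - 1) * px) {
    stop("AP stripe exceeds image bounds", call. = FALSE)
  }
  if (g$dv_center_um - g$dv_width_um / 2 < 0 ||
      g$dv_center_um + g$dv_width_um / 2 > (h - 1) * px) {
    stop("DV stripe exceeds image bounds", call. = FALSE)
  }
  in_ap_col <- col_um >= g$ap_center_um - g$ap_width_um / 2 &
    col_um < g$ap_center_um + g$ap_width_um / 2
  in_dv_row <- row_um >= g$dv_center_um - g$dv_width_um / 2 &
    row_um < g$dv_center_um + g$dv_width_um / 2
  apb <- matrix(rep(in_ap_col, each = h), h, w)
  dvb <- matrix(rep(in_dv_row, times = w), h, w)
  inside <- matrix(TRUE, h, w)
  if (g$margin_um > 0) {
    inside <- outer(row_um >= g$margin_um & row_um <= (h - 1) * px - g$margin_um,
                    col_um >= g$margin_um & col_um <= (w - 1) * px - g$margin_um,
                    "&")
  }
  apb <- apb & inside; dvb <- dvb & inside
  # dorsal = rows above the DV line, anterior = columns left of the AP line
  dorsal <- matrix(rep(row_um < g$dv_center_um, times = w), h, w)
  anterior <- matrix(rep(col_um < g$ap_center_um, each = h), h, w)
  no <- inside & !apb & !dvb
  labels <- matrix("outside", h, w)
  labels[no & dorsal & anterior] <- "NO_DA"
  labels[no & dorsal & !anterior] <- "NO_DP"
  labels[no & !dorsal & anterior] <- "NO_VA"
  labels[no & !dorsal & !anterior] <- "NO_VP"
  labels[apb & !dvb] <- "APB"
  labels[dvb & !apb] <- "DVB"
  labels[apb & dvb] <- "ORG"
  masks <- list(APB = apb, DVB = dvb, ORG = apb & dvb,
                NO_DA = no & dorsal & anterior, NO_DP = no & dorsal & !anterior,
                NO_VA = no & !dorsal & anterior, NO_VP = no & !dorsal & !anterior,
                outside = !inside)
  structure(list(labels = labels, masks = masks, geometry = g,
                 height_px = h, width_px = w, pixel_size_um = px),
            class = "pouch_labels")
}

#' Attach region kinetics to a label image
#'
#' @param labels A [build_pouch_labels()] result.
#' @param kinetics List of [region_kinetics()], one per label present in the
#'   image (the `outside` label needs none and is rendered dark).
#' @return A `scene_truth` object with `$labels`, `$kinetics` (named by
#'   label) and a `true_eta_map(t_min)` evaluator.
#' @export
scene_truth <- function(labels, kinetics) {
  stopifnot(inherits(labels, "pouch_labels"))
  if (inherits(kinetics, "region_kinetics")) kinetics <- list(kinetics)
  names(kinetics) <- vapply(kinetics, `[[`, character(1), "label")
  present <- setdiff(unique(as.vector(labels$labels)), "outside")
  missing <- setdiff(present, names(kinetics))
  if (length(missing)) {
    stop("no kinetics supplied for label(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(list(labels = labels, kinetics = kinetics),
            class = "scene_truth")
}

#' Per-pixel true efficiency map at a time since drug addition
#'
#' @param truth A [scene_truth()].
#' @param t_min Minutes since drug addition; negative values give the
#'   pre-drug plateau (`max_eta`). `outside` pixels are `NA`.
#' @return Matrix of true efficiencies.
#' @export
true_eta_map <- function(truth, t_min) {
  stopifnot(inherits(truth, "scene_truth"), length(t_min) == 1L)
  lab <- truth$labels$labels
  eta <- matrix(NA_real_, nrow(lab), ncol(lab))
  for (nm in names(truth$kinetics)) {
    kin <- truth$kinetics[[nm]]
    val <- if (t_min <= 0) kin$max_eta else true_eta(kin, t_min)
    eta[lab == nm] <- val
  }
  eta
}

#' Render the raw two-channel time-lapse of a scene
#'
#' Inverts the efficiency formula: a pixel with true efficiency `eta` and
#' total corrected intensity `T` has corrected donor `I_D = (1 - eta) * T`
#' and corrected FRET `I_FRET = eta * T`; the raw channels are
#' `I_D_raw = bg_donor + I_D + e` and
#' `I_F_raw = bg_fret + I_FRET + beta * I_D + e`, with `e` iid Gaussian
#' noise of SD `noise_sigma`, seeded from `spec$seed`. Frames acquired at or
#' before `drug_time_min` use the plateau `eta = max_eta`. Pixels labelled
#' `outside` carry no signal (background + noise only).
#'
#' @param spec A [scene_spec()].
#' @param truth A [scene_truth()] on the same geometry.
#' @return A `raw_timelapse`: `$donor`, `$fret` (H x W x T arrays, ADU),
#'   `$times_min`, plus pixel size, frame interval and drug time.
#' @export
render_frames <- function(spec, truth) {
  stopifnot(inherits(spec, "scene_spec"), inherits(truth, "scene_truth"))
  lab <- truth$labels
  if (lab$height_px != spec$height_px || lab$width_px != spec$width_px) {
    stop("spec and truth disagree on image size", call. = FALSE)
  }
  h <- spec$height_px; w <- spec$width_px; tt <- spec$n_frames
  times <- (seq_len(tt) - 1) * spec$frame_interval_min
  donor <- array(0, c(h, w, tt)); fret <- array(0, c(h, w, tt))
  with_local_seed(spec$seed, {
    for (k in seq_len(tt)) {
      eta <- true_eta_map(truth, times[k] - spec$drug_time_min)
      sig <- !is.na(eta)
      i_d <- matrix(0, h, w); i_f <- matrix(0, h, w)
      i_d[sig] <- (1 - eta[sig]) * spec$total_intensity
      i_f[sig] <- eta[sig] * spec$total_intensity
      d_raw <- spec$bg_donor + i_d
      f_raw <- spec$bg_fret + i_f + spec$beta * i_d
      if (spec$noise_sigma > 0) {
        d_raw <- d_raw + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
        f_raw <- f_raw + matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
      }
      donor[, , k] <- d_raw; fret[, , k] <- f_raw
    }
  })
  raw_timelapse(donor, fret, pixel_size_um = spec$pixel_size_um,
                frame_interval_min = spec$frame_interval_min,
                drug_time_min = spec$drug_time_min)
}

#' Construct a raw two-channel time-lapse container
#'
#' @param donor,fret H x W x T numeric arrays (ADU). Single frames may be
#'   passed as matrices.
#' @param pixel_size_um,frame_interval_min,drug_time_min Acquisition metadata.
#' @return A `raw_timelapse` object.
#' @export
raw_timelapse <- function(donor, fret, pixel_size_um = 0.22,
                          frame_interval_min = 1, drug_time_min = 0) {
  if (is.matrix(donor)) donor <- array(donor, c(dim(donor), 1L))
  if (is.matrix(fret)) fret <- array(fret, c(dim(fret), 1L))
  stopifnot(length(dim(donor)) == 3L, identical(dim(donor), dim(fret)))
  structure(list(
    donor = donor, fret = fret,
    pixel_size_um = pixel_size_um, frame_interval_min = frame_interval_min,
    drug_time_min = drug_time_min,
    times_min = (seq_len(dim(donor)[3]) - 1) * frame_interval_min
  ), class = "raw_timelapse")
}

#' @export
print.raw_timelapse <- function(x, ...) {
  d <- dim(x$donor)
  cat(sprintf(
    "raw_timelapse: %d x %d px, %d frames at %g min (drug at %g min), %g um/px\n",
    d[1], d[2], d[3], x$frame_interval_min, x$drug_time_min, x$pixel_size_um))
  invisible(x)
}

#' Render a donor-only calibration image pair
#'
#' Emulates the bleedthrough calibration acquisition on a specimen carrying
#' only the donor fluorophore: the donor channel records
#' `bg_donor + D + noise` and the FRET channel records only leaked donor
#' signal, `bg_fret + beta * D + noise`, with `D = total_intensity`
#' uniformly. With zero noise the pair satisfies
#' `bleedthrough = bg_fret + beta * (donor - bg_donor)` exactly.
#'
#' @param spec A [scene_spec()]; `beta`, backgrounds, `total_intensity`,
#'   `noise_sigma` and `seed` are used.
#' @return List with matrices `donor` and `bleedthrough` (ADU).
#' @export
render_calibration_pair <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$height_px; w <- spec$width_px
  d_sig <- matrix(spec$total_intensity, h, w)
  with_local_seed(spec$seed, {
    noise <- function() {
      if (spec$noise_sigma > 0) {
        matrix(stats::rnorm(h * w, 0, spec$noise_sigma), h, w)
      } else {
        matrix(0, h, w)
      }
    }
    donor <- spec$bg_donor + d_sig + noise()
    bth <- spec$bg_fret + spec$beta * d_sig + noise()
  })
  list(donor = donor, bleedthrough = bth)
}

#' Simulate noisy per-region efficiency traces without rendering images
#'
#' Draws, for each virtual disc and region, the four-parameter-logistic trace
#' sampled at the acquisition frames plus iid Gaussian trace noise. This is
#' the fast cohort generator used for power/null calibrations of the
#' downstream fits; [render_frames()] is its image-level counterpart.
#'
#' @param kinetics List of [region_kinetics()] (one per region).
#' @param n_discs Number of virtual discs.
#' @param n_frames,frame_interval_min,drug_time_min Acquisition grid.
#' @param noise_sigma SD of the additive trace noise (efficiency units).
#' @param seed RNG seed.
#' @return Data frame in trace format: `disc_id`, `region`, `frame`,
#'   `time_min`, `mean_eta`, `n_valid`; carries `drug_time_min` as an
#'   attribute.
#' @export
simulate_cohort_traces <- function(kinetics, n_discs = 26,
                                   n_frames = 130, frame_interval_min = 1,
                                   drug_time_min = 10, noise_sigma = 0.005,
                                   seed = 1L) {
  if (inherits(kinetics, "region_kinetics")) kinetics <- list(kinetics)
  times <- (seq_len(n_frames) - 1) * frame_interval_min
  out <- with_local_seed(seed, {
    do.call(rbind, lapply(seq_len(n_discs), function(d) {
      do.call(rbind, lapply(kinetics, function(kin) {
        eta <- ifelse(times <= drug_time_min, kin$max_eta,
                      true_eta(kin, pmax(times - drug_time_min, 0)))
        if (noise_sigma > 0) eta <- eta + stats::rnorm(n_frames, 0, noise_sigma)
        data.frame(disc_id = sprintf("disc%02d", d), region = kin$label,
                   frame = seq_len(n_frames) - 1L, time_min = times,
                   mean_eta = eta, n_valid = NA_integer_)
      }))
    }))
  })
  rownames(out) <- NULL
  attr(out, "drug_time_min") <- drug_time_min
  out
}
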