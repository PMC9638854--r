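# Per-pixel FRET efficiency from raw two-channel frames.
#
# Pipeline order (fixed): smooth -> background subtract -> bleedthrough
# correct -> ratio. With donor I_D and FRET-channel I_F after smoothing and
# background subtraction, the sensitized-emission correction is
#   I_FRET = I_F - beta * I_D,      eta = I_FRET / (I_D + I_FRET),
# where beta is the donor bleedthrough fraction measured on a donor-only
# specimen as beta = I_bth / I_D.

#' Configuration of the efficiency computation
#'
#' @param kernel_size Side of the square averaging kernel (odd; 5 matches the
#'   published analysis; 1 disables smoothing).
#' @param bg_donor,bg_fret Scalar background per channel (ADU), or `NULL` if
#'   `bg_roi` is given.
#' @param bg_roi Optional logical matrix; backgrounds are then the per-channel
#'   means over this ROI in the first frame. Exactly one of the scalar pair or
#'   `bg_roi` must be supplied.
#' @param beta Bleedthrough fraction (from [estimate_bleedthrough()]).
#' @param min_denominator Validity threshold (ADU) on the corrected total
#'   `I_D + I_FRET`; pixels below it are flagged invalid rather than divided.
#' @return A `correction_config` object.
#' @export
correction_config <- function(kernel_size = 5L, bg_donor = NULL, bg_fret = NULL,
                              bg_roi = NULL, beta = 0, min_denominator = 1) {
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 1L || kernel_size %% 2L == 0L) {
    stop("`kernel_size` must be odd and >= 1", call. = FALSE)
  }
  stopifnot_scalar(beta, "beta", nonneg = TRUE)
  stopifnot_scalar(min_denominator, "min_denominator", positive = TRUE)
  has_scalar <- !is.null(bg_donor) && !is.null(bg_fret)
  if (!has_scalar && is.null(bg_roi)) {
    stop("supply scalar backgrounds (`bg_donor`, `bg_fret`) or a `bg_roi`",
         call. = FALSE)
  }
  structure(list(kernel_size = kernel_size, bg_donor = bg_donor,
                 bg_fret = bg_fret, bg_roi = bg_roi, beta = beta,
                 min_denominator = min_denominator),
            class = "correction_config")
}

#' Moving-average smoothing with edge replication
#'
#' Square box filter of odd side `kernel_size`; the border is handled by
#' replicating edge pixels, so the output has the same shape and a constant
#' image is returned unchanged. Implemented as a direct shifted sum (exact to
#' summation order, no FFT).
#'
#' @param image Numeric matrix.
#' @param kernel_size Odd integer >= 1 (1 is the identity).
#' @return Smoothed matrix, same dimensions.
#' @export
smooth_image <- function(image, kernel_size = 5L) {
  stopifnot(is.matrix(image), is.numeric(image))
  kernel_size <- as.integer(kernel_size)
  if (kernel_size < 1L || kernel_size %% 2L == 0L) {
    stop("`kernel_size` must be odd and >= 1", call. = FALSE)
  }
  if (kernel_size == 1L) return(image)
  r <- (kernel_size - 1L) %/% 2L
  h <- nrow(image); w <- ncol(image)
  ridx <- c(rep(1L, r), seq_len(h), rep(h, r))
  cidx <- c(rep(1L, r), seq_len(w), rep(w, r))
  pad <- image[ridx, cidx, drop = FALSE]
  acc <- matrix(0, h, w)
  for (dr in 0:(kernel_size - 1L)) {
    for (dc in 0:(kernel_size - 1L)) {
      acc <- acc + pad[dr + seq_len(h), dc + seq_len(w), drop = FALSE]
    }
  }
  acc / (kernel_size^2)
}

#' Estimate the donor bleedthrough fraction
#'
#' From a donor-only calibration pair: background-subtract both images and
#' return the ratio of the masked means, `beta = mean(I_bth) / mean(I_D)`.
#' The ratio-of-means aggregation is robust to near-zero donor pixels (a
#' mean of per-pixel ratios would blow up on them).
#'
#' @param donor_image Donor-channel image of a donor-only specimen (ADU).
#' @param bleedthrough_image Matching FRET-channel image (leaked signal only).
#' @param mask Logical matrix of pixels to use; default all.
#' @param bg_donor,bg_fret Backgrounds subtracted before the ratio.
#' @return A `bleedthrough_estimate`: `beta`, `n_pixels_used`, `method`.
#' @export
estimate_bleedthrough <- function(donor_image, bleedthrough_image, mask = NULL,
                                  bg_donor = 0, bg_fret = 0) {
  stopifnot(is.matrix(donor_image), is.matrix(bleedthrough_image),
            identical(dim(donor_image), dim(bleedthrough_image)))
  if (is.null(mask)) mask <- matrix(TRUE, nrow(donor_image), ncol(donor_image))
  stopifnot(is.logical(mask), identical(dim(mask), dim(donor_image)))
  n <- sum(mask)
  if (n < 1L) stop("`mask` selects no pixels", call. = FALSE)
  d_mean <- mean(donor_image[mask] - bg_donor)
  b_mean <- mean(bleedthrough_image[mask] - bg_fret)
  if (d_mean <= 0) {
    stop("background-subtracted donor mean is not positive; check mask/backgrounds",
         call. = FALSE)
  }
  structure(list(beta = b_mean / d_mean, n_pixels_used = n,
                 method = "ratio_of_means"),
            class = "bleedthrough_estimate")
}

#' @export
print.bleedthrough_estimate <- function(x, ...) {
  cat(sprintf("bleedthrough beta = %.5f (%s, %d pixels)\n",
              x$beta, x$method, x$n_pixels_used))
  invisible(x)
}

#' Compute the per-pixel FRET efficiency stack
#'
#' Per frame: smooth both channels, subtract backgrounds, correct the FRET
#' channel for donor bleedthrough (`I_FRET = I_F - beta * I_D`) and form
#' `eta = I_FRET / (I_D + I_FRET)`. Pixels whose corrected total falls below
#' `min_denominator`, or whose efficiency leaves `[0, 1]` by more than 1e-9
#' (i.e. beyond floating error), are flagged invalid and carried as `NA` —
#' never silently zeroed; excursions within 1e-9 are clipped.
#'
#' @param raw A [raw_timelapse()].
#' @param cfg A [correction_config()].
#' @return An `efficiency_stack`: `$eta` (H x W x T, `NA` = invalid),
#'   `$valid` (logical array), `$times_min`, `$drug_time_min`,
#'   `$pixel_size_um`, `$backgrounds` (the scalars actually used).
#' @export
compute_efficiency <- function(raw, cfg) {
  stopifnot(inherits(raw, "raw_timelapse"), inherits(cfg, "correction_config"))
  d <- dim(raw$donor); h <- d[1]; w <- d[2]; tt <- d[3]
  if (!is.null(cfg$bg_roi)) {
    stopifnot(is.logical(cfg$bg_roi), identical(dim(cfg$bg_roi), c(h, w)))
    if (!any(cfg$bg_roi)) stop("background ROI selects no pixels", call. = FALSE)
    bgd <- mean(raw$donor[, , 1][cfg$bg_roi])
    bgf <- mean(raw$fret[, , 1][cfg$bg_roi])
  } else {
    bgd <- cfg$bg_donor; bgf <- cfg$bg_fret
  }
  eta <- array(NA_real_, d); valid <- array(FALSE, d)
  tol <- 1e-9
  for (k in seq_len(tt)) {
    i_d <- smooth_image(raw$donor[, , k], cfg$kernel_size) - bgd
    i_f <- smooth_image(raw$fret[, , k], cfg$kernel_size) - bgf
    i_fret <- i_f - cfg$beta * i_d
    denom <- i_d + i_fret
    ok <- denom >= cfg$min_denominator
    e <- matrix(NA_real_, h, w)
    e[ok] <- i_fret[ok] / denom[ok]
    inband <- ok & e >= -tol & e <= 1 + tol
    inband[is.na(inband)] <- FALSE
    e[!inband] <- NA_real_
    e[inband] <- pmin(pmax(e[inband], 0), 1)
    if (!any(inband)) {
      warning(sprintf("frame %d: no valid pixels", k), call. = FALSE)
    }
    eta[, , k] <- e; valid[, , k] <- inband
  }
  structure(list(eta = eta, valid = valid, times_min = raw$times_min,
                 drug_time_min = raw$drug_time_min,
                 pixel_size_um = raw$pixel_size_um,
                 backgrounds = c(donor = bgd, fret = bgf),
                 beta = cfg$beta, kernel_size = cfg$kernel_size),
            class = "efficiency_stack")
}

#' @export
print.efficiency_stack <- function(x, ...) {
  d <- dim(x$eta)
  cat(sprintf(
    "efficiency_stack: %d x %d px, %d frames; %.1f%% valid pixels; beta = %.4f\n",
    d[1], d[2], d[3], 100 * mean(x$valid), x$beta))
  invisible(x)
}

#' Calibrate the sensor efficiency floor from an ATP-insensitive sensor
#'
#' The lowest reliably recorded efficiency is defined from the distribution
#' of efficiencies of an ATP-insensitive sensor variant as the Gaussian mean
#' minus twice the SD. The Gaussian may be fitted by sample moments
#' (default) or by least squares to the density histogram; on Gaussian data
#' the two agree closely.
#'
#' @param eta_values Numeric vector of efficiencies (>= 100 values).
#' @param method `"moments"` or `"histogram"`.
#' @param bins Histogram bin count for `method = "histogram"`.
#' @return The floor value (mean - 2 SD), with attributes `mean`, `sd`,
#'   `method`, `n`.
#' @export
calibrate_floor <- function(eta_values, method = c("moments", "histogram"),
                            bins = 64L) {
  method <- match.arg(method)
  eta_values <- eta_values[is.finite(eta_values)]
  if (length(eta_values) < 100L) {
    stop("need at least 100 efficiency values to calibrate the floor",
         call. = FALSE)
  }
  m <- mean(eta_values); s <- stats::sd(eta_values)
  if (s == 0) {
    warning("degenerate sample (SD = 0); returning the mean", call. = FALSE)
    return(structure(m, mean = m, sd = 0, method = method,
                     n = length(eta_values)))
  }
  if (method == "histogram") {
    hh <- graphics::hist(eta_values, breaks = bins, plot = FALSE)
    df <- data.frame(x = hh$mids, y = hh$density)
    fit <- minpack.lm::nlsLM(
      y ~ stats::dnorm(x, mu, sigma),
      data = df, start = list(mu = m, sigma = s),
      lower = c(min(df$x), s / 100), upper = c(max(df$x), diff(range(df$x))),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    m <- unname(cf["mu"]); s <- unname(cf["sigma"])
  }
  structure(m - 2 * s, mean = m, sd = s, method = method,
            n = length(eta_values))
}
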