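# Constrained four-parameter-logistic (4PL) fitting of post-drug
# efficiency decline.
#
#   f(t) = base + (max - base) / (1 + (t_half / t)^n)
#
# base is fixed at the calibrated sensor floor (0.2827 by default), max is a
# fitted plateau bounded above by 0.7 (the highest reliably recorded mean
# efficiency), t_half is the half-life in minutes and n the Hill
# coefficient. The efficiency declines, so n is negative; a more negative n
# is a steeper transition at t_half. Time is re-expressed as minutes since
# drug addition, with the first post-drug frame at t = frame interval, so
# the t = 0 singularity never enters the residual.

#' Fitting configuration
#'
#' @param base_fixed Fixed lower asymptote (calibrated sensor floor).
#' @param max_upper_bound Upper bound on the fitted plateau.
#' @param ftol Cost-reduction tolerance of the least-squares solver.
#' @param max_iter Iteration cap.
#' @param hill_grid Restart grid of Hill starting values tried in order when
#'   the first attempt does not converge.
#' @return A `fit_config` object.
#' @export
fit_config <- function(base_fixed = 0.2827, max_upper_bound = 0.7,
                       ftol = 1e-10, max_iter = 200L,
                       hill_grid = c(-1, -2, -5)) {
  stopifnot_scalar(base_fixed, "base_fixed", positive = TRUE)
  stopifnot_scalar(max_upper_bound, "max_upper_bound", positive = TRUE)
  if (!(base_fixed < max_upper_bound && max_upper_bound <= 1)) {
    stop("require 0 < base_fixed < max_upper_bound <= 1", call. = FALSE)
  }
  structure(list(base_fixed = base_fixed, max_upper_bound = max_upper_bound,
                 ftol = ftol, max_iter = as.integer(max_iter),
                 hill_grid = hill_grid),
            class = "fit_config")
}

#' Four-parameter logistic curve
#'
#' `f(t) = base + (max_eta - base) / (1 + (t_half / t)^hill)`. At
#' `t = t_half` the value is `(base + max_eta) / 2` for any Hill
#' coefficient (the midpoint identity). `t = 0` is handled by the
#' continuous limit, which for `hill < 0` equals `max_eta`.
#'
#' @param t Time(s) since drug addition, minutes (>= 0).
#' @param base,max_eta Lower and upper asymptotes.
#' @param t_half Half-life, minutes (> 0).
#' @param hill Hill coefficient (nonzero; negative for decay).
#' @return Curve value(s).
#' @export
four_pl <- function(t, base, max_eta, t_half, hill) {
  if (t_half <= 0) stop("`t_half` must be > 0", call. = FALSE)
  if (hill == 0) stop("`hill` must be nonzero", call. = FALSE)
  base + (max_eta - base) / (1 + (t_half / t)^hill)
}

fit_result <- function(cfg, max_eta = NA_real_, t_half = NA_real_,
                       hill = NA_real_, rss = NA_real_, n_points = 0L,
                       converged = FALSE, message = "",
                       t_half_beyond_window = NA, increasing = NA) {
  structure(list(base = cfg$base_fixed, max_eta = max_eta, t_half = t_half,
                 hill = hill, rss = rss, n_points = as.integer(n_points),
                 converged = converged, message = message,
                 t_half_beyond_window = t_half_beyond_window,
                 increasing = increasing),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf(
    "4PL fit: base %.4f (fixed), max %.4f, t_half %.3f min, hill %.3f\n",
    x$base, x$max_eta, x$t_half, x$hill))
  cat(sprintf("  rss %.3g over %d points; converged: %s%s\n",
              x$rss, x$n_points, x$converged,
              if (isTRUE(x$t_half_beyond_window)) " (t_half beyond window)" else ""))
  invisible(x)
}

#' Fit the constrained 4PL to one post-drug region trace
#'
#' Uses the frames with `time_min > drug_time_min`, re-expressed as minutes
#' since drug addition. Missing values are dropped from the residual, not
#' interpolated. The fit is bounded trust-region least squares with `base`
#' fixed, `base < max_eta <= max_upper_bound`,
#' `t_half` in `(0, 10 x duration]` and `hill` in `[-50, 50]`. Starting
#' values: `max0` = mean of the first five post-drug points (capped at the
#' plateau bound), `t_half0` = first crossing of `(base + max0)/2` (else
#' half the duration), `hill0 = -2`, with a deterministic restart grid on
#' `hill0` if the first attempt fails. A fit whose half-life lands on a
#' bound, or that fails to converge, is reported with `converged = FALSE`;
#' a half-life beyond the observation window, or a positive Hill
#' coefficient (rising trace), is flagged.
#'
#' @param trace Trace data frame (`time_min`, `mean_eta`; see
#'   [extract_trace()]), with `drug_time_min` as an attribute or supplied
#'   explicitly.
#' @param cfg A [fit_config()].
#' @param drug_time_min Drug-addition time (minutes since acquisition
#'   start); defaults to the trace attribute.
#' @return A `logistic_fit`.
#' @export
fit_decay <- function(trace, cfg = fit_config(), drug_time_min = NULL) {
  stopifnot(is.data.frame(trace), all(c("time_min", "mean_eta") %in% names(trace)))
  if (is.null(drug_time_min)) drug_time_min <- attr(trace, "drug_time_min")
  if (is.null(drug_time_min)) {
    stop("`drug_time_min` not supplied and not carried by the trace", call. = FALSE)
  }
  keep <- trace$time_min > drug_time_min & !is.na(trace$mean_eta)
  t <- trace$time_min[keep] - drug_time_min
  y <- trace$mean_eta[keep]
  if (length(t) < 8L) stop("need at least 8 post-drug points", call. = FALSE)
  if (any(y < 0 | y > 1)) stop("trace values must lie in [0, 1]", call. = FALSE)
  if (all(y < cfg$base_fixed + 0.01)) stop("already at floor", call. = FALSE)
  duration <- max(t)
  base <- cfg$base_fixed
  max0 <- min(mean(y[seq_len(min(5L, length(y)))]), cfg$max_upper_bound)
  max0 <- max(max0, base + 1e-3)
  half_level <- (base + max0) / 2
  cross <- which(y <= half_level)
  t_half0 <- if (length(cross)) t[cross[1]] else duration / 2
  lower <- c(max_eta = base + 1e-6, t_half = 1e-6, hill = -50)
  upper <- c(max_eta = cfg$max_upper_bound, t_half = 10 * duration, hill = 50)
  dat <- data.frame(t = t, y = y)
  attempt <- function(hill0) {
    tryCatch(
      minpack.lm::nlsLM(
        y ~ base + (max_eta - base) / (1 + (t_half / t)^hill),
        data = dat,
        start = list(max_eta = max0, t_half = t_half0, hill = hill0),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(
          ftol = cfg$ftol, ptol = cfg$ftol, maxiter = cfg$max_iter)),
      error = function(e) e)
  }
  # rising traces need a positive Hill start; the sign is left free
  late <- mean(y[t > duration / 2]); early <- mean(y[t <= duration / 2])
  direction <- if (late > early) 1 else -1
  starts <- direction * abs(unique(c(-2, cfg$hill_grid)))
  fit <- NULL; msg <- ""
  for (h0 in starts) {
    res <- attempt(h0)
    if (!inherits(res, "error")) { fit <- res; break }
    msg <- conditionMessage(res)
  }
  if (is.null(fit)) {
    return(fit_result(cfg, n_points = length(t), converged = FALSE,
                      message = paste("solver failed:", msg)))
  }
  cf <- stats::coef(fit)
  rss <- sum(stats::resid(fit)^2)
  at_bound <- cf["t_half"] >= upper["t_half"] * (1 - 1e-6) ||
    cf["t_half"] <= 1e-5 || abs(cf["hill"]) >= 50 * (1 - 1e-6)
  conv <- isTRUE(fit$convInfo$isConv) && !at_bound
  fit_result(cfg,
             max_eta = unname(cf["max_eta"]), t_half = unname(cf["t_half"]),
             hill = unname(cf["hill"]), rss = rss, n_points = length(t),
             converged = conv,
             message = if (at_bound) "parameter at bound" else
               fit$convInfo$stopMessage,
             t_half_beyond_window = unname(cf["t_half"] > duration),
             increasing = unname(cf["hill"] > 0))
}

#' Fit a cohort of traces, per disc and for each region's mean trace
#'
#' One fit per disc x region plus one fit of each region's mean trace,
#' where the mean trace is the unweighted mean over discs per timepoint.
#' Per-trace failures are recorded (`converged = FALSE` with the message),
#' never abort the cohort.
#'
#' @param traces Row-bound trace data frame (see [extract_trace()] /
#'   [simulate_cohort_traces()]).
#' @param cfg A [fit_config()].
#' @param drug_time_min Drug time; defaults to the traces attribute.
#' @return Data frame with columns `disc_id`, `region`, `level` ("disc" or
#'   "mean"), `base`, `max_eta`, `t_half_min`, `hill`, `rss`, `n_points`,
#'   `converged`, `t_half_beyond_window`, `message`.
#' @export
fit_cohort <- function(traces, cfg = fit_config(), drug_time_min = NULL) {
  stopifnot(is.data.frame(traces))
  if (is.null(drug_time_min)) drug_time_min <- attr(traces, "drug_time_min")
  one <- function(tr, disc, region, level) {
    f <- tryCatch(fit_decay(tr, cfg, drug_time_min = drug_time_min),
                  error = function(e) fit_result(
                    cfg, n_points = sum(!is.na(tr$mean_eta)),
                    converged = FALSE, message = conditionMessage(e)))
    data.frame(disc_id = disc, region = region, level = level,
               base = f$base, max_eta = f$max_eta, t_half_min = f$t_half,
               hill = f$hill, rss = f$rss, n_points = f$n_points,
               converged = f$converged,
               t_half_beyond_window = f$t_half_beyond_window,
               message = f$message)
  }
  per_disc <- do.call(rbind, lapply(
    split(traces, list(traces$disc_id, traces$region), drop = TRUE),
    function(tr) one(tr, tr$disc_id[1], tr$region[1], "disc")))
  mean_fits <- do.call(rbind, lapply(split(traces, traces$region), function(tr) {
    agg <- stats::aggregate(mean_eta ~ frame + time_min, data = tr,
                            FUN = mean, na.action = stats::na.omit)
    agg <- agg[order(agg$time_min), ]
    one(agg, "mean", tr$region[1], "mean")
  }))
  out <- rbind(per_disc, mean_fits)
  rownames(out) <- NULL
  out
}
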