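# Region schemes for the wing-disc pouch and mean-efficiency trace
# extraction.
#
# The organizer scheme places nine circular ROIs of 20 um diameter: three
# along the anterior-posterior (AP) boundary, three along the dorsal-ventral
# (DV) boundary sharing the central circle (five distinct organizer
# circles), and four non-organizer circles at the quadrant midpoints.
# Composite regions (APB, DVB, ORG, NO) average the constituent ROI means
# ("mean of means", unweighted), whereas compartments (D, V and their
# anterior/posterior splits) pool pixels directly.

#' Build the nine-ROI organizer scheme
#'
#' The central circle sits at the AP x DV boundary intersection; two more
#' circles lie along each boundary direction at `+/- spacing_um`; four
#' non-organizer circles sit at the quadrant midpoints of the pouch bounding
#' box. Coordinates are 0-based `(row, col)` pixels.
#'
#' @param intersection Numeric `(row, col)`, 0-based pixels: the AP x DV
#'   boundary crossing.
#' @param ap_dir,dv_dir Direction vectors `(drow, dcol)` along the AP and DV
#'   boundary lines; must not be parallel. Defaults: AP boundary vertical
#'   (`c(1, 0)`), DV boundary horizontal (`c(0, 1)`).
#' @param spacing_um Centre-to-centre spacing along each boundary; default
#'   `1.5 * diameter_um` so circles are disjoint.
#' @param diameter_um ROI diameter (20 um in the published scheme).
#' @param pixel_size_um Pixel size.
#' @param image_shape `c(height, width)` in pixels.
#' @param pouch_bbox Optional `c(row_min, col_min, row_max, col_max)` (0-based)
#'   bounding box of the pouch; default the full image. Non-organizer circles
#'   are placed midway between the intersection and its corners.
#' @param dorsal_polygon,ventral_polygon Optional n x 2 matrices of `(row,
#'   col)` vertices outlining the compartments, for [compartment_traces()].
#' @param anterior_point Optional `(row, col)` known to lie in the anterior
#'   compartment; defaults to the lower-column side of the AP line.
#' @return A `roi_scheme`: `$circles` (data frame `role`, `row`, `col`),
#'   `$members` (composite region -> roles), geometry fields, and the
#'   compartment landmarks.
#' @export
make_roi_scheme <- function(intersection, ap_dir = c(1, 0), dv_dir = c(0, 1),
                            spacing_um = NULL, diameter_um = 20,
                            pixel_size_um = 0.22, image_shape,
                            pouch_bbox = NULL,
                            dorsal_polygon = NULL, ventral_polygon = NULL,
                            anterior_point = NULL) {
  stopifnot(length(intersection) == 2L, length(image_shape) == 2L)
  stopifnot_scalar(diameter_um, "diameter_um", positive = TRUE)
  if (is.null(spacing_um)) spacing_um <- 1.5 * diameter_um
  stopifnot_scalar(spacing_um, "spacing_um", positive = TRUE)
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n == 0) stop("direction vector must be nonzero", call. = FALSE)
    v / n
  }
  u_ap <- unit(ap_dir); u_dv <- unit(dv_dir)
  cross <- u_ap[1] * u_dv[2] - u_ap[2] * u_dv[1]
  if (abs(cross) < 1e-8) {
    stop("AP and DV boundary directions are parallel", call. = FALSE)
  }
  s_px <- spacing_um / pixel_size_um
  if (is.null(pouch_bbox)) pouch_bbox <- c(0, 0, image_shape[1] - 1, image_shape[2] - 1)
  corners <- rbind(c(pouch_bbox[1], pouch_bbox[2]), c(pouch_bbox[1], pouch_bbox[4]),
                   c(pouch_bbox[3], pouch_bbox[2]), c(pouch_bbox[3], pouch_bbox[4]))
  centers <- rbind(
    C   = intersection,
    AP1 = intersection - s_px * u_ap,
    AP2 = intersection + s_px * u_ap,
    DV1 = intersection - s_px * u_dv,
    DV2 = intersection + s_px * u_dv,
    NO1 = (intersection + corners[1, ]) / 2,
    NO2 = (intersection + corners[2, ]) / 2,
    NO3 = (intersection + corners[3, ]) / 2,
    NO4 = (intersection + corners[4, ]) / 2)
  r_px <- diameter_um / 2 / pixel_size_um
  out_of_bounds <- centers[, 1] - r_px < 0 | centers[, 1] + r_px > image_shape[1] - 1 |
    centers[, 2] - r_px < 0 | centers[, 2] + r_px > image_shape[2] - 1
  if (any(out_of_bounds)) {
    stop("circle(s) out of image bounds: ",
         paste(rownames(centers)[out_of_bounds], collapse = ", "), call. = FALSE)
  }
  org <- centers[c("C", "AP1", "AP2", "DV1", "DV2"), ]
  if (nrow(unique(round(org, 6))) != 5L) {
    stop("organizer circles are not distinct; increase `spacing_um`", call. = FALSE)
  }
  circles <- data.frame(role = rownames(centers),
                        row = centers[, 1], col = centers[, 2],
                        row.names = NULL)
  structure(list(
    circles = circles,
    members = list(APB = c("AP1", "C", "AP2"), DVB = c("DV1", "C", "DV2"),
                   ORG = c("AP1", "AP2", "C", "DV1", "DV2"),
                   NO = c("NO1", "NO2", "NO3", "NO4")),
    diameter_um = diameter_um, pixel_size_um = pixel_size_um,
    image_shape = as.integer(image_shape),
    intersection = as.numeric(intersection),
    ap_dir = u_ap, dv_dir = u_dv,
    dorsal_polygon = dorsal_polygon, ventral_polygon = ventral_polygon,
    anterior_point = anterior_point
  ), class = "roi_scheme")
}

#' @export
print.roi_scheme <- function(x, ...) {
  cat(sprintf("roi_scheme: 9 circles of %g um on a %d x %d image (%g um/px)\n",
              x$diameter_um, x$image_shape[1], x$image_shape[2], x$pixel_size_um))
  print(x$circles)
  invisible(x)
}

#' Rasterize a circular ROI
#'
#' A pixel belongs to the circle if its centre (0-based integer coordinate)
#' lies within the radius, inclusive — reproducible and orientation
#' independent.
#'
#' @param center `(row, col)`, 0-based pixels.
#' @param radius_px Radius in pixels.
#' @param shape `c(height, width)`.
#' @return Logical matrix.
#' @export
circle_mask <- function(center, radius_px, shape) {
  rows <- matrix(rep(0:(shape[1] - 1), times = shape[2]), shape[1], shape[2])
  cols <- matrix(rep(0:(shape[2] - 1), each = shape[1]), shape[1], shape[2])
  (rows - center[1])^2 + (cols - center[2])^2 <= radius_px^2
}

#' Pixel masks of the scheme's circles
#'
#' @param scheme A [make_roi_scheme()].
#' @return Named list of logical matrices, one per circle role.
#' @export
scheme_masks <- function(scheme) {
  stopifnot(inherits(scheme, "roi_scheme"))
  r_px <- scheme$diameter_um / 2 / scheme$pixel_size_um
  masks <- lapply(seq_len(nrow(scheme$circles)), function(i) {
    circle_mask(c(scheme$circles$row[i], scheme$circles$col[i]), r_px,
                scheme$image_shape)
  })
  names(masks) <- scheme$circles$role
  masks
}

frame_region_mean <- function(eta_frame, mask) {
  v <- eta_frame[mask]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    c(mean_eta = NA_real_, n_valid = 0)
  } else {
    c(mean_eta = mean(v), n_valid = length(v))
  }
}

#' Extract a mean-efficiency time trace for one region
#'
#' For a plain mask, the trace is the mean of valid pixels per frame. For a
#' list of masks (a composite region such as APB, DVB, ORG or NO), each
#' frame's value is the unweighted mean of the constituent ROI means — the
#' ROIs are "averaged together", not pixel-pooled. Frames with no valid
#' pixel give `NA`.
#'
#' @param eta An `efficiency_stack` from [compute_efficiency()].
#' @param region Logical matrix, or a named list of logical matrices.
#' @param label Region name recorded in the trace.
#' @param disc_id Disc identifier.
#' @return Trace data frame: `disc_id`, `region`, `frame`, `time_min`,
#'   `mean_eta`, `n_valid` (summed over constituents), with the drug time as
#'   an attribute.
#' @export
extract_trace <- function(eta, region, label = "region", disc_id = "disc01") {
  stopifnot(inherits(eta, "efficiency_stack"))
  masks <- if (is.list(region)) region else list(region)
  shp <- dim(eta$eta)[1:2]
  for (m in masks) {
    stopifnot(is.logical(m), identical(dim(m), shp))
    if (!any(m)) stop("empty region mask", call. = FALSE)
  }
  tt <- dim(eta$eta)[3]
  vals <- matrix(NA_real_, tt, length(masks))
  nval <- matrix(0, tt, length(masks))
  for (k in seq_len(tt)) {
    fr <- eta$eta[, , k]
    for (j in seq_along(masks)) {
      s <- frame_region_mean(fr, masks[[j]])
      vals[k, j] <- s["mean_eta"]; nval[k, j] <- s["n_valid"]
    }
  }
  if (all(nval == 0)) stop("region has no valid pixels in any frame", call. = FALSE)
  mean_eta <- rowMeans(vals)   # NA if any constituent ROI is empty that frame
  out <- data.frame(disc_id = disc_id, region = label,
                    frame = seq_len(tt) - 1L, time_min = eta$times_min,
                    mean_eta = mean_eta, n_valid = as.integer(rowSums(nval)))
  attr(out, "drug_time_min") <- eta$drug_time_min
  out
}

#' Traces of the composite organizer-scheme regions
#'
#' @param eta An `efficiency_stack`.
#' @param scheme A [make_roi_scheme()].
#' @param regions Composite regions to extract (subset of APB, DVB, ORG, NO).
#' @param disc_id Disc identifier.
#' @return Row-bound trace data frame (one region per block).
#' @export
roi_traces <- function(eta, scheme, regions = c("APB", "DVB", "ORG", "NO"),
                       disc_id = "disc01") {
  stopifnot(inherits(scheme, "roi_scheme"))
  regions <- match.arg(regions, c("APB", "DVB", "ORG", "NO"), several.ok = TRUE)
  masks <- scheme_masks(scheme)
  out <- do.call(rbind, lapply(regions, function(rg) {
    extract_trace(eta, masks[scheme$members[[rg]]], label = rg,
                  disc_id = disc_id)
  }))
  attr(out, "drug_time_min") <- eta$drug_time_min
  out
}

polygon_mask <- function(polygon, shape) {
  stopifnot(is.matrix(polygon), ncol(polygon) == 2L)
  if (nrow(polygon) < 3L) stop("degenerate polygon (< 3 vertices)", call. = FALSE)
  rows <- rep(0:(shape[1] - 1), times = shape[2])
  cols <- rep(0:(shape[2] - 1), each = shape[1])
  inside <- mgcv::in.out(rbind(polygon, polygon[1, , drop = FALSE]),
                         cbind(rows, cols))
  matrix(inside, shape[1], shape[2])
}

#' Compartment and sub-compartment traces (D, V, DA, DP, VA, VP)
#'
#' Dorsal and ventral compartments come from the scheme's freehand-style
#' polygons; the anterior/posterior sub-compartments intersect each polygon
#' with the half-plane of the AP boundary line through the scheme's
#' intersection point. Compartment means pool pixels directly (single
#' region, no sub-ROI averaging).
#'
#' @param eta An `efficiency_stack`.
#' @param scheme A [make_roi_scheme()] carrying `dorsal_polygon` and
#'   `ventral_polygon`.
#' @param disc_id Disc identifier.
#' @return Trace data frame with regions D, V, DA, DP, VA, VP.
#' @export
compartment_traces <- function(eta, scheme, disc_id = "disc01") {
  stopifnot(inherits(scheme, "roi_scheme"))
  if (is.null(scheme$dorsal_polygon) || is.null(scheme$ventral_polygon)) {
    stop("scheme carries no compartment polygons", call. = FALSE)
  }
  shp <- dim(eta$eta)[1:2]
  d_mask <- polygon_mask(scheme$dorsal_polygon, shp)
  v_mask <- polygon_mask(scheme$ventral_polygon, shp)
  rows <- matrix(rep(0:(shp[1] - 1), times = shp[2]), shp[1], shp[2])
  cols <- matrix(rep(0:(shp[2] - 1), each = shp[1]), shp[1], shp[2])
  # signed side of the AP boundary line through the intersection
  side <- (rows - scheme$intersection[1]) * scheme$ap_dir[2] -
    (cols - scheme$intersection[2]) * scheme$ap_dir[1]
  ap <- if (!is.null(scheme$anterior_point)) {
    p <- scheme$anterior_point
    ref <- (p[1] - scheme$intersection[1]) * scheme$ap_dir[2] -
      (p[2] - scheme$intersection[2]) * scheme$ap_dir[1]
    if (ref == 0) stop("`anterior_point` lies on the AP line", call. = FALSE)
    sign(ref)
  } else {
    # default: anterior = lower-column side
    med <- stats::median(side[cols < scheme$intersection[2]])
    if (is.na(med) || med == 0) 1 else sign(med)
  }
  anterior <- side * ap > 0
  regions <- list(D = d_mask, V = v_mask,
                  DA = d_mask & anterior, DP = d_mask & !anterior,
                  VA = v_mask & anterior, VP = v_mask & !anterior)
  out <- do.call(rbind, lapply(names(regions), function(rg) {
    extract_trace(eta, regions[[rg]], label = rg, disc_id = disc_id)
  }))
  attr(out, "drug_time_min") <- eta$drug_time_min
  out
}

#' Read a landmark sidecar JSON into an ROI scheme
#'
#' The sidecar carries point/polygon coordinates (0-based `(row, col)`)
#' instead of interactive clicking, so region definitions are scriptable:
#' fields `intersection`, optional `ap_dir`, `dv_dir`, `spacing_um`,
#' `diameter_um`, `pixel_size_um`, `image_shape`, `pouch_bbox`,
#' `dorsal_polygon`, `ventral_polygon`, `anterior_point`.
#'
#' @param path JSON file path.
#' @return A [make_roi_scheme()] result.
#' @export
read_landmarks <- function(path) {
  lm <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("intersection", "image_shape", "pixel_size_um")
  miss <- setdiff(req, names(lm))
  if (length(miss)) stop("landmark file missing: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  poly <- function(x) {
    if (is.null(x)) return(NULL)
    if (is.matrix(x)) x else do.call(rbind, lapply(x, as.numeric))
  }
  make_roi_scheme(
    intersection = as.numeric(lm$intersection),
    ap_dir = if (is.null(lm$ap_dir)) c(1, 0) else as.numeric(lm$ap_dir),
    dv_dir = if (is.null(lm$dv_dir)) c(0, 1) else as.numeric(lm$dv_dir),
    spacing_um = lm$spacing_um,
    diameter_um = if (is.null(lm$diameter_um)) 20 else lm$diameter_um,
    pixel_size_um = lm$pixel_size_um,
    image_shape = as.numeric(lm$image_shape),
    pouch_bbox = if (is.null(lm$pouch_bbox)) NULL else as.numeric(lm$pouch_bbox),
    dorsal_polygon = poly(lm$dorsal_polygon),
    ventral_polygon = poly(lm$ventral_polygon),
    anterior_point = if (is.null(lm$anterior_point)) NULL else as.numeric(lm$anterior_point))
}

#' Write a landmark sidecar JSON
#'
#' @param scheme A [make_roi_scheme()] result.
#' @param path Output path.
#' @export
write_landmarks <- function(scheme, path) {
  stopifnot(inherits(scheme, "roi_scheme"))
  lm <- list(intersection = scheme$intersection,
             ap_dir = scheme$ap_dir, dv_dir = scheme$dv_dir,
             diameter_um = scheme$diameter_um,
             pixel_size_um = scheme$pixel_size_um,
             image_shape = scheme$image_shape)
  if (!is.null(scheme$dorsal_polygon)) lm$dorsal_polygon <- scheme$dorsal_polygon
  if (!is.null(scheme$ventral_polygon)) lm$ventral_polygon <- scheme$ventral_polygon
  if (!is.null(scheme$anterior_point)) lm$anterior_point <- scheme$anterior_point
  jsonlite::write_json(lm, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
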