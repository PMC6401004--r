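#' Convert retardance to surface height
#'
#' In the reflective double-pass geometry a mirror displacement `dz`
#' produces the retardance \eqn{\Phi = 4\pi\,\delta z/\lambda}, so
#' \deqn{\delta z = \lambda\,\Phi/(4\pi).}
#'
#' @param phase an unwrapped `phase_map` (or numeric vector/matrix of
#'   unwrapped phase values, radians).
#' @param wavelength wavelength, nm.
#' @return A `height_map` (list with `height` in nm and `pitch`) when given
#'   a `phase_map`; otherwise numeric heights in nm.
#' @export
phase_to_height <- function(phase, wavelength = 600) {
  if (inherits(phase, "phase_map")) {
    if (phase$wrapped)
      stop("phase_to_height: phase map is wrapped; unwrap() it first")
    return(structure(list(height = wavelength * phase$phase / (4 * pi),
                          pitch = phase$pitch),
                     class = "height_map"))
  }
  wavelength * phase / (4 * pi)
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map>  %d x %d px, pitch %.4g um, range [%.3g, %.3g] nm\n",
              nrow(x$height), ncol(x$height), x$pitch,
              min(x$height), max(x$height)))
  invisible(x)
}

#' Convert retardance to dry-mass surface density (Davies relation)
#'
#' The non-aqueous (dry) mass per unit area of a cell is proportional to
#' the optical phase it imprints, through the specific refractive increment
#' alpha: \deqn{\rho = \lambda\,\Phi/(2\pi\,\alpha\,\mathrm{passes}).}
#' The conventional increment attributed to Davies & Wilkins,
#' alpha = 0.18 um^3/pg, is the default; `passes = 2` accounts for the
#' reflective geometry in which light traverses the specimen twice.
#'
#' @param phase an unwrapped `phase_map` or numeric phase values, radians.
#' @param wavelength wavelength, nm.
#' @param alpha specific refractive increment, um^3/pg (> 0).
#' @param passes number of passes through the specimen (1 or 2).
#' @return A `drymass_map` (list with `density` in pg/um^2 and `pitch`)
#'   when given a `phase_map`; otherwise numeric densities.
#' @export
phase_to_drymass <- function(phase, wavelength = 600, alpha = 0.18, passes = 2) {
  if (alpha <= 0) stop("phase_to_drymass: alpha must be positive")
  if (!passes %in% c(1, 2)) stop("phase_to_drymass: passes must be 1 or 2")
  lam_um <- wavelength / 1000
  conv <- function(p) lam_um * p / (2 * pi * alpha * passes)
  if (inherits(phase, "phase_map")) {
    if (phase$wrapped)
      stop("phase_to_drymass: phase map is wrapped; unwrap() it first")
    return(structure(list(density = conv(phase$phase), pitch = phase$pitch),
                     class = "drymass_map"))
  }
  conv(phase)
}

#' @export
print.drymass_map <- function(x, ...) {
  cat(sprintf("<drymass_map>  %d x %d px, pitch %.4g um, total mass %.4g pg\n",
              nrow(x$density), ncol(x$density), x$pitch,
              sum(x$density) * x$pitch^2))
  invisible(x)
}

#' Inverse Davies relation (density to phase)
#'
#' @param density dry-mass surface density, pg/um^2.
#' @inheritParams phase_to_drymass
#' @return phase in radians.
#' @export
drymass_to_phase <- function(density, wavelength = 600, alpha = 0.18, passes = 2) {
  2 * pi * alpha * passes * density / (wavelength / 1000)
}

# centers of an n_rois lattice (3x3 for 9) placed uniformly over the
# interior of an ny x nx grid, leaving room for the half-size of the ROI
.roi_lattice <- function(ny, nx, n_rois, half_px) {
  k <- round(sqrt(n_rois))
  stopifnot(k * k == n_rois)
  cy <- round(seq(half_px + 1, ny - half_px, length.out = k + 2)[2:(k + 1)])
  cx <- round(seq(half_px + 1, nx - half_px, length.out = k + 2)[2:(k + 1)])
  expand.grid(cy = cy, cx = cx)
}

#' Temporal-stability protocol
#'
#' The precision protocol of the piezo-free calibration: the ROI-mean
#' height is tracked through the stack in `n_rois` circular regions (3x3
#' lattice) whose radius equals the diffraction-spot radius
#' 0.61 lambda / NA (1.22 um for 600 nm at NA 0.3), and the standard
#' deviation of each time series is reported, summarized as mean +/- sd
#' across ROIs.
#'
#' @param stack list of `height_map`s (>= 2 frames, common geometry).
#' @param n_rois number of ROIs (a square number; default 9).
#' @param roi_radius ROI radius, um.
#' @return A `stability_report`: list with `per_roi` (sd per ROI, nm),
#'   `sigma` (mean across ROIs), `spread` (sd across ROIs), `n_frames`,
#'   `roi` geometry.
#' @export
temporal_stability <- function(stack, n_rois = 9, roi_radius = 1.22) {
  stopifnot(length(stack) >= 2L)
  h1 <- stack[[1L]]
  ny <- nrow(h1$height); nx <- ncol(h1$height)
  r_px <- max(1, roi_radius / h1$pitch)
  if (2 * r_px + 2 > min(ny, nx))
    stop("temporal_stability: ROI does not fit in the grid")
  cen <- .roi_lattice(ny, nx, n_rois, ceiling(r_px))
  masks <- lapply(seq_len(nrow(cen)), function(i) {
    (col(h1$height) - cen$cx[i])^2 + (row(h1$height) - cen$cy[i])^2 <= r_px^2
  })
  series <- vapply(stack, function(h) {
    vapply(masks, function(m) mean(h$height[m]), 0)
  }, numeric(length(masks)))
  per_roi <- apply(series, 1L, stats::sd)
  structure(list(per_roi = per_roi, sigma = mean(per_roi),
                 spread = stats::sd(per_roi), n_frames = length(stack),
                 roi = list(kind = "disk", radius_um = roi_radius,
                            centers = cen)),
            class = "stability_report")
}

#' Spatial-noise protocol
#'
#' Background precision over the field: the per-pixel standard deviation of
#' the height inside `n_rois` square blank areas (default nine 20 x 20 um^2
#' regions equally distributed over the field of view), summarized as
#' mean +/- sd across ROIs.
#'
#' @param hmap a `height_map`.
#' @param n_rois number of ROIs (square number).
#' @param roi_size ROI edge length, um.
#' @return A `stability_report` (sd values in nm).
#' @export
spatial_noise <- function(hmap, n_rois = 9, roi_size = 20) {
  ny <- nrow(hmap$height); nx <- ncol(hmap$height)
  half <- round(roi_size / hmap$pitch / 2)
  if (2 * half + 2 > min(ny, nx))
    stop("spatial_noise: ROIs do not fit in the grid")
  cen <- .roi_lattice(ny, nx, n_rois, half)
  per_roi <- vapply(seq_len(nrow(cen)), function(i) {
    stats::sd(hmap$height[(cen$cy[i] - half):(cen$cy[i] + half - 1),
                          (cen$cx[i] - half):(cen$cx[i] + half - 1)])
  }, 0)
  structure(list(per_roi = per_roi, sigma = mean(per_roi),
                 spread = stats::sd(per_roi), n_frames = 1L,
                 roi = list(kind = "square", size_um = roi_size,
                            centers = cen)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report>  sigma = %.3g +/- %.3g nm over %d ROIs (%s), %d frame(s)\n",
              x$sigma, x$spread, length(x$per_roi), x$roi$kind, x$n_frames))
  invisible(x)
}

#' Mean-error / RMSE accuracy report
#'
#' Per-displacement-step accuracy of reconstructed heights against ground
#' truth across independent repeats: ME is the mean signed error and RMSE
#' the root-mean-square error at each step.
#'
#' @param measured numeric matrix (steps x repeats) of measured heights, nm,
#'   or a vector for a single repeat.
#' @param truth vector of ground-truth heights, nm (length = steps).
#' @return An `accuracy_report`: list with `truth`, `me`, `rmse`,
#'   `n_repeats`.
#' @export
accuracy_metrics <- function(measured, truth) {
  if (is.vector(measured)) measured <- matrix(measured, ncol = 1L)
  if (nrow(measured) != length(truth))
    stop("accuracy_metrics: measured and truth step counts differ")
  err <- measured - truth
  me <- rowMeans(err)
  rmse <- sqrt(rowMeans(err^2))
  structure(list(truth = truth, me = me, rmse = rmse,
                 n_repeats = ncol(measured)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report>  %d steps x %d repeats; max |ME| = %.3g nm, max RMSE = %.3g nm\n",
              length(x$truth), x$n_repeats, max(abs(x$me)), max(x$rmse)))
  invisible(x)
}

#' Serialize a report to JSON or CSV
#' @param report a `stability_report` or `accuracy_report`.
#' @param path output path; `.json` or `.csv` chosen from the extension.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.csv$", path)) {
    df <- if (inherits(report, "accuracy_report"))
      data.frame(truth_nm = report$truth, me_nm = report$me, rmse_nm = report$rmse)
    else data.frame(roi = seq_along(report$per_roi), sigma_nm = report$per_roi)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  invisible(path)
}
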