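#' Sampled broadband illumination spectrum
#'
#' The broadband source (tungsten-halogen lamp behind a bandpass filter) is
#' represented by a discrete set of spectral lines with normalized weights.
#' `make_spectrum()` samples a Gaussian band of the given center and FWHM at
#' `n_samples` equally spaced wavelengths spanning +/- 2 standard
#' deviations.  With `n_samples = 1` a monochromatic line at the center is
#' returned.  The default (600 nm center, 50 nm FWHM) corresponds to a
#' coherence length \eqn{\lambda^2/\Delta\lambda = 7.2} um.
#'
#' @param center central wavelength, nm.
#' @param fwhm full width at half maximum of the band, nm.
#' @param n_samples number of spectral lines.
#' @return An object of class `spectrum`: data.frame with columns
#'   `wavelength` (nm, strictly increasing) and `weight` (sums to 1).
#' @examples
#' s <- make_spectrum(600, 50, 21)
#' sum(s$weight)
#' coherence_length(s)
#' @export
make_spectrum <- function(center = 600, fwhm = 50, n_samples = 7) {
  stopifnot(length(center) == 1L, length(fwhm) == 1L, length(n_samples) == 1L)
  if (!is.finite(center) || center <= 0)
    stop("make_spectrum: center wavelength must be positive")
  if (fwhm < 0) stop("make_spectrum: fwhm must be nonnegative")
  n_samples <- as.integer(n_samples)
  if (n_samples < 1L) stop("make_spectrum: n_samples must be >= 1")
  if (n_samples == 1L || fwhm == 0) {
    s <- data.frame(wavelength = center, weight = 1)
  } else {
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    wl <- seq(center - 2 * sigma, center + 2 * sigma, length.out = n_samples)
    w <- exp(-(wl - center)^2 / (2 * sigma^2))
    s <- data.frame(wavelength = wl, weight = w / sum(w))
  }
  attr(s, "center") <- center
  attr(s, "fwhm") <- fwhm
  class(s) <- c("spectrum", "data.frame")
  s
}

#' @rdname make_spectrum
#' @param spectrum a `spectrum` object.
#' @return `coherence_length()`: coherence length in um
#'   (\eqn{\lambda_c^2/\Delta\lambda}); `Inf` for a monochromatic spectrum.
#' @export
coherence_length <- function(spectrum) {
  center <- attr(spectrum, "center")
  fwhm <- attr(spectrum, "fwhm")
  if (is.null(center)) center <- sum(spectrum$wavelength * spectrum$weight)
  if (is.null(fwhm) || fwhm == 0 || nrow(spectrum) == 1L) return(Inf)
  (center^2 / fwhm) / 1000   # nm -> um
}

# pixel-center coordinate grids, origin at grid center, x rightward (columns),
# y downward (rows); 0-based index i maps to (i - (n-1)/2) * pitch
.scene_coords <- function(nx, ny, pitch) {
  x <- (seq_len(nx) - 1 - (nx - 1) / 2) * pitch
  y <- (seq_len(ny) - 1 - (ny - 1) / 2) * pitch
  list(x = matrix(rep(x, each = ny), ny, nx),
       y = matrix(rep(y, times = nx), ny, nx))
}

.new_scene <- function(nx, ny, pitch, phi_s, phi_r, truth, kind,
                       amp_s = 1, amp_r = 1, params = list()) {
  structure(list(nx = nx, ny = ny, pitch = pitch,
                 phi_s = phi_s, phi_r = phi_r,
                 amp_s = amp_s, amp_r = amp_r,
                 truth = truth, kind = kind, params = params),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec '%s'>  %d x %d px, pitch %.4g um (field %.4g x %.4g um)\n",
              x$kind, x$nx, x$ny, x$pitch, x$nx * x$pitch, x$ny * x$pitch))
  invisible(x)
}

#' Retardance of a scene at one wavelength
#'
#' The restorable quantity of every scene is the retardance
#' \eqn{\Phi_s - \Phi_r} between the sample- and reference-arm phase maps.
#'
#' @param scene a `scene_spec`.
#' @param wavelength wavelength in nm.
#' @return matrix of retardance values, radians.
#' @export
scene_retardance <- function(scene, wavelength) {
  scene$phi_s(wavelength) - scene$phi_r(wavelength)
}

#' Piezo-displaced mirror scene
#'
#' Flat mirror displaced by `dz` nanometers along the optical axis in a
#' reflective double-pass geometry: the sample-arm phase is the uniform,
#' wavelength-dependent piston \eqn{\Phi_s(\lambda) = 4\pi\,dz/\lambda}; the
#' reference arm is unmodulated.  The wavelength dependence is what produces
#' coherence gating in broadband holograms.  Displacements are restricted to
#' the 0-1 um range over which a piezo transducer operates reliably.
#'
#' @param grid grid size in pixels (scalar or `c(ny, nx)`).
#' @param pitch object-space pixel pitch, um.
#' @param dz mirror displacement, nm (|dz| <= 1000).
#' @return A `scene_spec` whose ground truth is the height `dz`.
#' @export
mirror_scene <- function(grid = 256, pitch = 0.5, dz = 0) {
  g <- .grid_dims(grid)
  if (!is.finite(dz) || abs(dz) > 1000)
    stop("mirror_scene: dz must be finite and |dz| <= 1000 nm")
  phi_s <- function(wavelength) {
    matrix(4 * pi * dz / wavelength, g$ny, g$nx)
  }
  phi_r <- function(wavelength) matrix(0, g$ny, g$nx)
  .new_scene(g$nx, g$ny, pitch, phi_s, phi_r,
             truth = list(height_nm = dz), kind = "mirror",
             params = list(dz = dz))
}

.grid_dims <- function(grid) {
  grid <- as.integer(grid)
  if (length(grid) == 1L) grid <- c(grid, grid)
  stopifnot(all(grid >= 8L))
  list(ny = grid[1L], nx = grid[2L])
}

#' Spatial-light-modulator retardance scene
#'
#' Piecewise-constant sample phase programmed per SLM pixel.  `phase_matrix`
#' holds one retardance value (radians) per SLM pixel; the pixel lattice is
#' centered on the field.  The phase is wavelength-independent over the
#' illumination band (liquid-crystal dispersion neglected, consistent with
#' a single reported retardance per pixel).  Optional Gaussian blur of width
#' `crosstalk_sigma` emulates inter-pixel crosstalk.  The reference arm is
#' unmodulated.
#'
#' @param grid grid size in pixels.
#' @param pitch object-space pixel pitch, um.
#' @param pixel_size SLM pixel size, um.  The device pixel pitch is not a
#'   quantity this package can derive; 20 um is typical for reflective
#'   liquid-crystal-on-silicon modulators.
#' @param phase_matrix matrix of programmed phases, radians, one per SLM
#'   pixel (rows = y, cols = x).
#' @param crosstalk_sigma Gaussian crosstalk width, um (0 = none).
#' @return A `scene_spec`; ground truth carries the programmed matrix and
#'   the per-pixel footprint masks.
#' @export
slm_scene <- function(grid = 512, pitch = 0.25, pixel_size = 20,
                      phase_matrix, crosstalk_sigma = 0) {
  g <- .grid_dims(grid)
  if (!all(is.finite(phase_matrix)))
    stop("slm_scene: phase_matrix must be finite")
  if (pixel_size < pitch)
    stop("slm_scene: pixel_size smaller than the grid pitch")
  phase_matrix <- as.matrix(phase_matrix)
  co <- .scene_coords(g$nx, g$ny, pitch)
  npy <- nrow(phase_matrix); npx <- ncol(phase_matrix)
  # SLM pixel lattice centered on the field
  ix <- floor(co$x / pixel_size + npx / 2)
  iy <- floor(co$y / pixel_size + npy / 2)
  inside <- ix >= 0 & ix < npx & iy >= 0 & iy < npy
  phase <- matrix(0, g$ny, g$nx)
  idx <- cbind(iy[inside] + 1L, ix[inside] + 1L)
  phase[inside] <- phase_matrix[idx]
  if (crosstalk_sigma > 0)
    phase <- .gaussian_blur(phase, crosstalk_sigma / pitch)
  force(phase)
  phi_s <- function(wavelength) phase
  phi_r <- function(wavelength) matrix(0, g$ny, g$nx)
  .new_scene(g$nx, g$ny, pitch, phi_s, phi_r,
             truth = list(phase_matrix = phase_matrix,
                          pixel_size = pixel_size,
                          pixel_index_x = ix, pixel_index_y = iy,
                          inside = inside),
             kind = "slm",
             params = list(pixel_size = pixel_size,
                           crosstalk_sigma = crosstalk_sigma))
}

# separable Gaussian blur, sigma in pixels, replicate edges
.gaussian_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- exp(-((-r):r)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  blur1 <- function(v) {
    n <- length(v)
    ve <- c(rep(v[1L], r), v, rep(v[n], r))
    as.numeric(stats::filter(ve, k, sides = 2))[(r + 1L):(r + n)]
  }
  m <- apply(m, 2L, blur1)
  t(apply(m, 1L, blur1))
}

#' Polarization-directed (geometric-phase) lens scene
#'
#' Thin flat lens whose anisotropy axis orientation encodes the single-pass
#' geometric phase \eqn{\phi(x,y) = -\pi r^2/(\lambda_0 f)} inside the
#' aperture.  The element is polarization directed: the two circular
#' components receive \eqn{+\phi} and \eqn{-\phi} (complex-conjugate
#' waves), so the restorable retardance is \eqn{2\phi}.  The geometric
#' phase is achromatic, hence wavelength-independent across the band.
#'
#' @param grid grid size in pixels.
#' @param pitch object-space pixel pitch, um.
#' @param focal_length design focal length, mm (nonzero).
#' @param design_wavelength design wavelength, nm.
#' @param aperture_halfwidth aperture half-width, mm; `Inf` fills the field.
#' @param aperture `"square"` (full field-of-view style) or `"circular"`.
#' @return A `scene_spec`; ground truth carries the single-pass phase map,
#'   the focal length and the aperture mask.
#' @export
gp_lens_scene <- function(grid = 1024, pitch = 500 / 1024, focal_length = 100,
                          design_wavelength = 600, aperture_halfwidth = Inf,
                          aperture = c("square", "circular")) {
  g <- .grid_dims(grid)
  aperture <- match.arg(aperture)
  if (focal_length == 0) stop("gp_lens_scene: focal_length must be nonzero")
  co <- .scene_coords(g$nx, g$ny, pitch)
  lam_um <- design_wavelength / 1000
  f_um <- focal_length * 1000
  a_um <- aperture_halfwidth * 1000
  mask <- if (is.infinite(a_um)) {
    matrix(TRUE, g$ny, g$nx)
  } else if (aperture == "square") {
    abs(co$x) <= a_um & abs(co$y) <= a_um
  } else {
    (co$x^2 + co$y^2) <= a_um^2
  }
  phi <- -pi * (co$x^2 + co$y^2) / (lam_um * f_um)
  phi[!mask] <- 0
  force(phi)
  phi_s <- function(wavelength) phi
  phi_r <- function(wavelength) -phi
  .new_scene(g$nx, g$ny, pitch, phi_s, phi_r,
             truth = list(single_pass_phase = phi, focal_length_mm = focal_length,
                          design_wavelength_nm = design_wavelength,
                          aperture_mask = mask),
             kind = "gp_lens",
             params = list(focal_length = focal_length,
                           design_wavelength = design_wavelength,
                           aperture_halfwidth = aperture_halfwidth,
                           aperture = aperture))
}

#' Live-cell phantom with known dry mass
#'
#' Generates `n_cells` non-overlapping smooth blobs of dry-mass surface
#' density.  Each cell is a disk-supported superposition of Gaussian
#' kernels (equivalently, a disk of radius `radius` convolved with a
#' Gaussian of width `rim_sigma`), giving a flat interior and a compact
#' smooth rim so that thresholded segmentation captures nearly all of the
#' injected mass.  The per-cell amplitude is normalized on the grid so each
#' integrated mass matches its target exactly.  The sample-arm phase is
#' obtained by inverting the Davies relation for the double-pass geometry
#' (see [phase_to_drymass()]).
#'
#' @param grid grid size in pixels.
#' @param pitch object-space pixel pitch, um.
#' @param n_cells number of cells (>= 1).
#' @param total_mass_range range of per-cell dry mass, pg.
#' @param seed integer seed; the phantom is deterministic given the seed.
#' @param radius_range range of cell disk radii, um.
#' @param rim_sigma Gaussian rim width, um.
#' @param wavelength wavelength used for the phase encoding, nm.
#' @param alpha specific refractive increment, um^3/pg.
#' @param passes number of passes through the specimen (2 = reflective).
#' @param area_growth per-frame fractional area growth (for time-lapse
#'   phantoms; area grows while mean density falls when mass grows slower).
#' @param mass_growth per-frame fractional mass growth.
#' @param frame frame index encoded in the ground-truth table.
#' @return A `scene_spec`; ground truth carries the density map and a
#'   `cell_table` (frame, label, area_um2, mean_density_pg_um2,
#'   total_mass_pg) plus cell centers and radii.
#' @export
cell_phantom <- function(grid = 256, pitch = 0.5, n_cells = 5,
                         total_mass_range = c(150, 300), seed = 1,
                         radius_range = c(7, 11), rim_sigma = 1.5,
                         wavelength = 600, alpha = 0.18, passes = 2,
                         area_growth = 0, mass_growth = 0, frame = 1L) {
  g <- .grid_dims(grid)
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) stop("cell_phantom: n_cells must be >= 1")
  set.seed(as.integer(seed))
  fx <- g$nx * pitch; fy <- g$ny * pitch
  growth_r <- sqrt(1 + area_growth)^(frame - 1L)
  growth_m <- (1 + mass_growth)^(frame - 1L)
  radii <- stats::runif(n_cells, radius_range[1L], radius_range[2L]) * growth_r
  masses <- stats::runif(n_cells, total_mass_range[1L], total_mass_range[2L]) * growth_m
  # rejection placement: centers pairwise separated and clear of the border
  centers <- matrix(NA_real_, n_cells, 2L)
  margin <- radii + 4 * rim_sigma
  placed <- 0L
  for (tries in seq_len(400L * n_cells)) {
    i <- placed + 1L
    if (2 * margin[i] >= min(fx, fy)) break   # cell cannot fit at all
    cand <- c(stats::runif(1, -fx / 2 + margin[i], fx / 2 - margin[i]),
              stats::runif(1, -fy / 2 + margin[i], fy / 2 - margin[i]))
    ok <- TRUE
    if (placed > 0L) {
      d <- sqrt((centers[seq_len(placed), 1L] - cand[1L])^2 +
                (centers[seq_len(placed), 2L] - cand[2L])^2)
      ok <- all(d > radii[seq_len(placed)] + radii[i] + 8 * rim_sigma)
    }
    if (ok) {
      centers[i, ] <- cand
      placed <- i
      if (placed == n_cells) break
    }
  }
  if (placed < n_cells)
    stop("cell_phantom: could not place ", n_cells,
         " non-overlapping cells; reduce n_cells or radii")
  co <- .scene_coords(g$nx, g$ny, pitch)
  density <- matrix(0, g$ny, g$nx)
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    r <- sqrt((co$x - centers[i, 1L])^2 + (co$y - centers[i, 2L])^2)
    # smoothed-disk profile: erf rim around a flat top
    prof <- 0.5 * (1 - .erf((r - radii[i]) / (sqrt(2) * rim_sigma)))
    s <- sum(prof) * pitch^2
    blob <- prof * (masses[i] / s)       # exact mass on the grid
    density <- density + blob
    area_i <- pi * radii[i]^2
    rows[[i]] <- data.frame(frame = frame, label = i,
                            area_um2 = area_i,
                            mean_density_pg_um2 = masses[i] / area_i,
                            total_mass_pg = masses[i])
  }
  tab <- cell_table(do.call(rbind, rows))
  lam_um <- wavelength / 1000
  phase <- 2 * pi * alpha * passes * density / lam_um
  force(phase)
  phi_s <- function(wl) phase
  phi_r <- function(wl) matrix(0, g$ny, g$nx)
  .new_scene(g$nx, g$ny, pitch, phi_s, phi_r,
             truth = list(density = density, cells = tab,
                          centers = centers, radii = radii,
                          wavelength = wavelength, alpha = alpha,
                          passes = passes),
             kind = "cells",
             params = list(n_cells = n_cells, seed = seed,
                           rim_sigma = rim_sigma,
                           area_growth = area_growth,
                           mass_growth = mass_growth, frame = frame))
}

.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Per-cell record table
#'
#' @param df data.frame with columns `frame`, `label`, `area_um2`,
#'   `mean_density_pg_um2`, `total_mass_pg`.
#' @return the data.frame classed as `cell_table`.
#' @export
cell_table <- function(df) {
  need <- c("frame", "label", "area_um2", "mean_density_pg_um2", "total_mass_pg")
  stopifnot(all(need %in% names(df)))
  if (any(df$area_um2 <= 0)) stop("cell_table: areas must be positive")
  if (anyDuplicated(df[, c("frame", "label")]))
    stop("cell_table: labels must be unique within a frame")
  class(df) <- c("cell_table", "data.frame")
  df
}

#' Serialize a scene descriptor to JSON
#'
#' Writes the generator name, parameters and seed so the scene can be
#' regenerated bit-for-bit; ground-truth maps are not embedded.
#'
#' @param scene a `scene_spec`.
#' @param path output path (`.json`).
#' @export
write_scene_descriptor <- function(scene, path) {
  desc <- list(kind = scene$kind, nx = scene$nx, ny = scene$ny,
               pitch = scene$pitch, params = scene$params)
  jsonlite::write_json(desc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
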