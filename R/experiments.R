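#' Default acquisition geometries for the study conditions
#'
#' The simulated instrument uses a fixed set of geometries, one per
#' experiment class, chosen once to match the reported hardware:
#' \itemize{
#' \item `mirror`: 512 x 512 px at 0.5 um object pitch (NA 0.3 Mirau
#'   objective, field 256 um), carrier 0.35 cycles/um along x, hard
#'   sideband filter of radius 0.15 cycles/um.  The filter sets the noise
#'   correlation length (~1/B = 6.7 um); the blank-area precision protocol
#'   averages noise patches inside 20 um ROIs, so the correlation length
#'   must stay well below the ROI size for the ROI statistics to be
#'   stable, which a quarter-Nyquist carrier cannot provide;
#' \item `mirror_small`: 256 x 256 px variant for frame-heavy time series;
#' \item `slm`: 512 x 512 px at 0.25 um pitch (field 128 um covering a
#'   block of 20 um SLM pixels), carrier 0.6 cycles/um, Gaussian-tapered
#'   filter of radius 0.15 cycles/um (sharp per-pixel phase steps demand a
#'   wide, ringing-free filter);
#' \item `lens`: 1024 x 1024 px covering the 0.5 x 0.5 mm^2 field of the
#'   4x/NA 0.1 objective (pitch ~0.49 um, the sampling of a 4-megapixel
#'   camera over that field), carrier 0.125 cycles/um, hard filter of
#'   radius 0.025 cycles/um (about twice the highest local fringe
#'   frequency of the f = 100 mm quadratic phase across this field), no
#'   apodization window (the quadratic pattern is edge-symmetric and a
#'   window's amplitude gradient distorts the phase over the wide 1/B
#'   kernel), and a 64 px border exclusion matching that kernel width;
#' \item `cells`: 512 x 512 px at 0.25 um pitch (field 128 um), carrier
#'   0.8 cycles/um with a Gaussian filter of radius 0.3 cycles/um: the
#'   steep few-um cell rims carry local fringe frequencies near
#'   0.3 cycles/um, and losing them makes the unwrapped interior drop
#'   whole 2 pi wrap counts.  The filter's spatial reach (~1 um) matches
#'   the diffraction limit of the NA 0.3 objective.
#' }
#'
#' @param name geometry name.
#' @return list with `grid`, `pitch`, `carrier`, `bandwidth`, `taper`.
#' @export
acquisition_geometry <- function(name = c("mirror", "mirror_small", "slm",
                                          "lens", "cells")) {
  switch(match.arg(name),
    mirror = list(grid = 512L, pitch = 0.5, carrier = c(0.35, 0),
                  bandwidth = 0.15, taper = "hard"),
    mirror_small = list(grid = 256L, pitch = 0.5, carrier = c(0.35, 0),
                        bandwidth = 0.15, taper = "hard"),
    slm = list(grid = 512L, pitch = 0.25, carrier = c(0.6, 0),
               bandwidth = 0.15, taper = "gaussian"),
    lens = list(grid = 1024L, pitch = 500 / 1024, carrier = c(0.125, 0),
                bandwidth = 0.025, taper = "hard", apodize = FALSE,
                border = 64L),
    cells = list(grid = 512L, pitch = 0.25, carrier = c(0.8, 0),
                 bandwidth = 0.3, taper = "gaussian"))
}

#' Calibrate the detector read-noise amplitude to a target background noise
#'
#' The spatial background noise of the instrument is summarized by the
#' blank-area height standard deviation sigma_Z.  This routine finds the
#' additive read-noise amplitude (relative to the unit-amplitude intensity
#' scale, see [form_hologram()]) that makes the full reconstruction chain
#' reproduce a given sigma_Z on a blank mirror hologram in the reference
#' (mirror) geometry.  Because intensity clipping at zero makes the
#' response mildly nonlinear, the scale is refined over a few fixed-point
#' iterations on pilot holograms; the returned amplitude is then a
#' property of the simulated camera and transfers to the other acquisition
#' geometries.
#'
#' @param target_sigma_z_nm target blank-area height std, nm.
#' @param geometry geometry list ([acquisition_geometry()]).
#' @param spectrum illumination spectrum.
#' @param seed seed for the pilot holograms.
#' @param iters fixed-point iterations.
#' @param n_pilot pilot holograms averaged per iteration.
#' @return read-noise amplitude (relative intensity units).
#' @export
calibrate_read_noise <- function(target_sigma_z_nm = 2.95,
                                 geometry = acquisition_geometry("mirror"),
                                 spectrum = make_spectrum(600, 50, 7),
                                 seed = 1, iters = 3, n_pilot = 4) {
  scene <- mirror_scene(geometry$grid, geometry$pitch, dz = 0)
  sigma <- target_sigma_z_nm * 4 * pi / 600 /
    sqrt(pi * geometry$bandwidth^2 * geometry$pitch^2 / 2)  # linear first guess
  for (i in seq_len(iters)) {
    got <- mean(vapply(seq_len(n_pilot), function(p) {
      h <- form_hologram(scene, spectrum, geometry$carrier,
                         noise = list(read_sigma = sigma),
                         seed = seed + 37L * i + p)
      pm <- reconstruct_phase(h, bandwidth = geometry$bandwidth,
                              taper = geometry$taper, background = 1)
      hm <- phase_to_height(pm, attr(spectrum, "center"))
      # calibrate against the protocol statistic itself (mean of the
      # nine 20x20 um^2 ROI standard deviations), not the full-field sd:
      # with few noise-correlation cells per ROI the ROI sd runs a few
      # percent low of the field sd
      spatial_noise(hm)$sigma
    }, 0))
    sigma <- sigma * target_sigma_z_nm / got
  }
  sigma
}

.interior <- function(m, border) {
  b <- min(border, floor((min(dim(m)) - 1) / 2))
  m[(b + 1L):(nrow(m) - b), (b + 1L):(ncol(m) - b)]
}

# derive a sub-stream seed without integer overflow for large user seeds
.subseed <- function(seed, mult, offset) {
  as.integer((as.numeric(seed) * mult + offset) %% 2147483647)
}

#' Temporal-stability experiment
#'
#' Simulates a stack of blank-mirror holograms whose only temporal
#' variation is a per-frame Gaussian piston drift (plus photon shot noise),
#' reconstructs every frame, converts to height and applies the
#' temporal-stability protocol.
#'
#' @param n_frames number of frames.
#' @param drift_nm per-frame piston drift standard deviation, nm.
#' @param photon_budget mean photons per pixel.
#' @param seed integer seed.
#' @param geometry acquisition geometry.
#' @param spectrum illumination spectrum.
#' @param n_rois,roi_radius passed to [temporal_stability()].
#' @return the `stability_report`.
#' @export
run_stability <- function(n_frames = 300, drift_nm = 0.83,
                          photon_budget = 1e4, seed = 1,
                          geometry = acquisition_geometry("mirror_small"),
                          spectrum = make_spectrum(600, 50, 7),
                          n_rois = 9, roi_radius = 1.22) {
  scene <- mirror_scene(geometry$grid, geometry$pitch, dz = 0)
  wl <- attr(spectrum, "center")
  stack <- lapply(seq_len(n_frames), function(f) {
    h <- form_hologram(scene, spectrum, geometry$carrier,
                       noise = list(drift_nm = drift_nm,
                                    photon_budget = photon_budget),
                       seed = .subseed(seed, 100003, f), frame = f)
    pm <- reconstruct_phase(h, bandwidth = geometry$bandwidth,
                            taper = geometry$taper)
    pm$wrapped <- FALSE  # blank scene: piston stays far from the wrap edge
    phase_to_height(pm, wl)
  })
  temporal_stability(stack, n_rois = n_rois, roi_radius = roi_radius)
}

#' Spatial-noise experiment
#'
#' Calibrates the read-noise amplitude against the target sigma_Z on pilot
#' holograms, then generates an independent blank hologram with the same
#' settings and applies the nine-ROI 20 x 20 um^2 spatial-noise protocol.
#'
#' @param target_sigma_z_nm calibration target, nm.
#' @param seed integer seed (the pilot uses a derived, disjoint seed).
#' @param geometry acquisition geometry.
#' @param spectrum illumination spectrum.
#' @param photon_budget mean photons per pixel.
#' @param n_rois,roi_size passed to [spatial_noise()].
#' @return list with the `stability_report` and the calibrated `read_sigma`.
#' @export
run_spatial_noise <- function(target_sigma_z_nm = 2.95, seed = 1,
                              geometry = acquisition_geometry("mirror"),
                              spectrum = make_spectrum(600, 50, 7),
                              photon_budget = 1e4,
                              n_rois = 9, roi_size = 20) {
  read_sigma <- calibrate_read_noise(target_sigma_z_nm, geometry, spectrum,
                                     seed = .subseed(seed, 7919, 0))
  scene <- mirror_scene(geometry$grid, geometry$pitch, dz = 0)
  h <- form_hologram(scene, spectrum, geometry$carrier,
                     noise = list(read_sigma = read_sigma,
                                  photon_budget = photon_budget),
                     seed = seed)
  pm <- reconstruct_phase(h, bandwidth = geometry$bandwidth,
                          taper = geometry$taper, background = 1)
  hm <- phase_to_height(pm, attr(spectrum, "center"))
  list(report = spatial_noise(hm, n_rois = n_rois, roi_size = roi_size),
       read_sigma = read_sigma)
}

#' Ground-truth accuracy experiment (piezo staircase)
#'
#' Simulates the mirror displaced from 0 to `max(steps_nm)` in the given
#' steps, several independent repeats, each frame with piston noise and
#' shot noise.  The piston retardance of each frame is estimated by the
#' circular mean and its 2*pi ambiguity is resolved against the commanded
#' transducer position (exactly how a staircase calibration is read out:
#' the measured phase is compared with the theoretical dependence, so the
#' wrap count is known as long as the height error stays below a quarter
#' wave).  Heights are computed at the central wavelength and per-step
#' ME/RMSE against ground truth is reported.
#'
#' @param steps_nm displacement steps, nm (excluding the 0 reference).
#' @param repeats number of independent repeats.
#' @param drift_nm piston noise per frame, nm.
#' @param photon_budget mean photons per pixel.
#' @param seed integer seed.
#' @param geometry acquisition geometry.
#' @param spectrum illumination spectrum.
#' @return the `accuracy_report`.
#' @export
run_accuracy <- function(steps_nm = seq(100, 1000, by = 100), repeats = 5,
                         drift_nm = 0.83, photon_budget = 1e4, seed = 1,
                         geometry = acquisition_geometry("mirror_small"),
                         spectrum = make_spectrum(600, 50, 7)) {
  wl <- attr(spectrum, "center")
  all_dz <- c(0, steps_nm)
  expected <- 4 * pi * all_dz / wl
  measured <- matrix(NA_real_, length(steps_nm), repeats)
  for (r in seq_len(repeats)) {
    pistons <- vapply(seq_along(all_dz), function(i) {
      scene <- mirror_scene(geometry$grid, geometry$pitch, dz = all_dz[i])
      h <- form_hologram(scene, spectrum, geometry$carrier,
                         noise = list(drift_nm = drift_nm,
                                      photon_budget = photon_budget),
                         seed = .subseed(seed, 104729, r * 1009 + i))
      piston_phase(reconstruct_phase(h, bandwidth = geometry$bandwidth,
                                     taper = geometry$taper))
    }, 0)
    series <- expected + .wrap(pistons - expected)
    series <- series - series[1L]       # reference position
    measured[, r] <- phase_to_height(series[-1L], wl)
  }
  accuracy_metrics(measured, steps_nm)
}

#' SLM retardance experiment
#'
#' Programs the given per-pixel phases on a centered SLM pixel lattice,
#' forms sample and non-addressed background holograms with
#' calibration-level read noise, reconstructs both, subtracts the
#' background (wrapped arithmetic), and reports the mean and standard
#' deviation of the restored phase over the interior of every programmed
#' pixel.  The interior margin (default 25% of the pixel size per side)
#' excludes the rim where optical resolution and electrical crosstalk mix
#' neighboring pixels.
#'
#' @param phase_matrix programmed SLM phases, radians (matrix).
#' @param read_sigma read-noise amplitude; NULL to calibrate against
#'   `target_sigma_z_nm` in the mirror geometry first.
#' @param target_sigma_z_nm calibration target when `read_sigma` is NULL.
#' @param photon_budget mean photons per pixel.
#' @param seed integer seed.
#' @param geometry acquisition geometry.
#' @param spectrum illumination spectrum.
#' @param pixel_size SLM pixel size, um.
#' @param interior_margin fraction of the pixel edge excluded per side.
#' @param crosstalk_sigma scene-level crosstalk blur, um.
#' @return list with `pixels` (data.frame: row, col, programmed, mean, sd,
#'   n_px), the background-subtracted `phase` map and `read_sigma`.
#' @export
run_slm <- function(phase_matrix, read_sigma = NULL, target_sigma_z_nm = 2.95,
                    photon_budget = 1e4, seed = 1,
                    geometry = acquisition_geometry("slm"),
                    spectrum = make_spectrum(600, 50, 7),
                    pixel_size = 20, interior_margin = 0.25,
                    crosstalk_sigma = 0) {
  if (is.null(read_sigma))
    read_sigma <- calibrate_read_noise(target_sigma_z_nm, seed = .subseed(seed, 7919, 0))
  phase_matrix <- as.matrix(phase_matrix)
  scene <- slm_scene(geometry$grid, geometry$pitch, pixel_size, phase_matrix,
                     crosstalk_sigma = crosstalk_sigma)
  blank <- slm_scene(geometry$grid, geometry$pitch, pixel_size,
                     matrix(0, nrow(phase_matrix), ncol(phase_matrix)))
  noise <- list(read_sigma = read_sigma, photon_budget = photon_budget)
  h <- form_hologram(scene, spectrum, geometry$carrier, noise = noise,
                     seed = .subseed(seed, 2, 1))
  h0 <- form_hologram(blank, spectrum, geometry$carrier, noise = noise,
                      seed = .subseed(seed, 2, 0))
  pm <- reconstruct_phase(h, bandwidth = geometry$bandwidth,
                          taper = geometry$taper)
  bg <- reconstruct_phase(h0, bandwidth = geometry$bandwidth,
                          taper = geometry$taper)
  diffp <- subtract_background(pm, reference = bg)
  # programmed strokes approach pi, so noisy values straddle the wrap edge;
  # unwrap the difference map and re-anchor its zero on the non-addressed area
  diffp <- unwrap(diffp)
  tr <- scene$truth
  addressed <- matrix(FALSE, nrow(diffp$phase), ncol(diffp$phase))
  for (rr in seq_len(nrow(phase_matrix)))
    for (cc in seq_len(ncol(phase_matrix)))
      if (phase_matrix[rr, cc] != 0)
        addressed <- addressed | (tr$inside & tr$pixel_index_y == (rr - 1L) &
                                    tr$pixel_index_x == (cc - 1L))
  bgsel <- !addressed
  bgsel[c(seq_len(16L), nrow(bgsel) - seq_len(16L) + 1L), ] <- FALSE
  bgsel[, c(seq_len(16L), ncol(bgsel) - seq_len(16L) + 1L)] <- FALSE
  # keep background pixels clear of the addressed rims
  bgsel <- bgsel & !(.gaussian_blur(addressed * 1,
                                    0.2 * pixel_size / geometry$pitch) > 1e-3)
  diffp$phase <- diffp$phase - mean(diffp$phase[bgsel])
  margin_px <- interior_margin * pixel_size / geometry$pitch
  rows <- list()
  for (rr in seq_len(nrow(phase_matrix))) {
    for (cc in seq_len(ncol(phase_matrix))) {
      if (phase_matrix[rr, cc] == 0) next
      inpix <- tr$inside & tr$pixel_index_y == (rr - 1L) &
        tr$pixel_index_x == (cc - 1L)
      # shrink to the interior: distance to the pixel's bounding box edge
      idx <- which(inpix, arr.ind = TRUE)
      ry <- range(idx[, 1L]); rx <- range(idx[, 2L])
      interior <- inpix &
        row(inpix) >= ry[1L] + margin_px & row(inpix) <= ry[2L] - margin_px &
        col(inpix) >= rx[1L] + margin_px & col(inpix) <= rx[2L] - margin_px
      vals <- diffp$phase[interior]
      rows[[length(rows) + 1L]] <-
        data.frame(row = rr, col = cc, programmed = phase_matrix[rr, cc],
                   mean = mean(vals), sd = stats::sd(vals),
                   n_px = length(vals))
    }
  }
  list(pixels = do.call(rbind, rows), phase = diffp, read_sigma = read_sigma)
}

#' Geometric-phase lens experiment
#'
#' End-to-end synthetic measurement of a polarization-directed lens:
#' scene, hologram with calibration-level read noise and shot noise,
#' demodulation, unwrapping, piston/tilt removal, and comparison with the
#' theoretical retardance 2*phi.  Reports the worst absolute deviation
#' over the field and along the two central cross-section profiles
#' (border excluded), and the focal length fitted to the single-pass
#' phase.
#'
#' @param focal_length design focal length, mm.
#' @param read_sigma read-noise amplitude; NULL to calibrate first.
#' @param target_sigma_z_nm calibration target when `read_sigma` is NULL.
#' @param photon_budget mean photons per pixel.
#' @param seed integer seed.
#' @param geometry acquisition geometry.
#' @param spectrum illumination spectrum.
#' @param border border exclusion, px.
#' @return list with `max_abs_err`, `max_abs_err_profiles`, `f_mm`,
#'   `phase` (the compensated retardance map), `theory`, `read_sigma`.
#' @export
run_lens <- function(focal_length = 100, read_sigma = NULL,
                     target_sigma_z_nm = 2.95, photon_budget = 1e4, seed = 1,
                     geometry = acquisition_geometry("lens"),
                     spectrum = make_spectrum(600, 50, 7), border = NULL) {
  if (is.null(read_sigma))
    read_sigma <- calibrate_read_noise(target_sigma_z_nm, seed = .subseed(seed, 7919, 0))
  if (is.null(border)) border <- if (is.null(geometry$border)) 16L else geometry$border
  wl <- attr(spectrum, "center")
  scene <- gp_lens_scene(geometry$grid, geometry$pitch, focal_length,
                         design_wavelength = wl)
  h <- form_hologram(scene, spectrum, geometry$carrier,
                     noise = list(read_sigma = read_sigma,
                                  photon_budget = photon_budget),
                     seed = seed)
  pm <- reconstruct_phase(h, bandwidth = geometry$bandwidth,
                          taper = geometry$taper,
                          apodize = !isFALSE(geometry$apodize))
  uw <- unwrap(pm)
  theory <- 2 * scene$truth$single_pass_phase
  # piston/tilt compensation against the theoretical profile
  resid <- phase_map(uw$phase - theory, uw$pitch, wrapped = FALSE)
  resid <- subtract_background(resid, poly_order = 1)
  err <- .interior(resid$phase, border)
  mid_r <- floor(nrow(err) / 2) + 1L
  mid_c <- floor(ncol(err) / 2) + 1L
  comp <- phase_map(theory + resid$phase, uw$pitch, wrapped = FALSE)
  ft <- fit_focal_length(single_pass_phase(comp), wl, border = border)
  list(max_abs_err = max(abs(err)),
       max_abs_err_profiles = max(abs(err[mid_r, ]), abs(err[, mid_c])),
       f_mm = ft$f_mm, phase = comp, theory = theory,
       read_sigma = read_sigma)
}

#' Time-lapse cell phantom experiment
#'
#' Generates a growing-cell phantom series, pushes every frame through the
#' hologram/reconstruction chain, converts to dry mass, segments, measures
#' and tracks.
#'
#' @param n_frames number of frames.
#' @param n_cells number of cells.
#' @param area_growth per-frame fractional area growth.
#' @param mass_growth per-frame fractional mass growth.
#' @param photon_budget mean photons per pixel.
#' @param seed integer seed.
#' @param geometry acquisition geometry.
#' @param spectrum illumination spectrum.
#' @return list with `trajectories`, per-frame `tables`, `labels`,
#'   `truth` tables.
#' @export
run_cells <- function(n_frames = 3, n_cells = 4, area_growth = 0.02,
                      mass_growth = 0.01, photon_budget = 1e4, seed = 1,
                      geometry = acquisition_geometry("cells"),
                      spectrum = make_spectrum(600, 50, 7),
                      radius_range = c(6, 9)) {
  wl <- attr(spectrum, "center")
  labels <- vector("list", n_frames)
  tables <- vector("list", n_frames)
  truth <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    scene <- cell_phantom(geometry$grid, geometry$pitch, n_cells = n_cells,
                          seed = seed, area_growth = area_growth,
                          mass_growth = mass_growth, frame = f,
                          wavelength = wl, radius_range = radius_range)
    h <- form_hologram(scene, spectrum, geometry$carrier,
                       noise = list(photon_budget = photon_budget),
                       seed = .subseed(seed, 613, f))
    pm <- reconstruct_phase(h, bandwidth = geometry$bandwidth,
                            taper = geometry$taper)
    uw <- subtract_background(unwrap(pm), poly_order = 1)
    # refit the background plane on cell-free pixels only; a plain fit is
    # biased upward by the cells and skims several percent off their mass
    uw <- subtract_background(uw, poly_order = 1,
                              mask = uw$phase < 0.1 * max(uw$phase))
    dm <- phase_to_drymass(uw, wl)
    labels[[f]] <- segment_cells(dm)
    tables[[f]] <- measure_cells(labels[[f]], dm, frame = f, expand = 5)
    truth[[f]] <- scene$truth$cells
  }
  traj <- if (n_frames >= 2L) track_cells(labels, tables) else NULL
  list(trajectories = traj, tables = tables, labels = labels, truth = truth)
}

#' Run a named experiment
#'
#' Dispatcher over the five study protocols; writes a provenance record
#' (experiment name, parameters, seed, package version) alongside any
#' outputs when `out_dir` is given.
#'
#' @param name one of `"stability"`, `"spatial-noise"`, `"accuracy"`,
#'   `"slm"`, `"lens"`, `"cells"`.
#' @param ... parameters forwarded to the `run_*` function.
#' @param seed integer seed.
#' @param out_dir optional output directory for reports + provenance.
#' @return the experiment result object.
#' @export
run_experiment <- function(name, ..., seed = 1, out_dir = NULL) {
  fun <- switch(name,
                "stability" = run_stability,
                "spatial-noise" = run_spatial_noise,
                "accuracy" = run_accuracy,
                "slm" = function(..., seed)
                  run_slm(phase_matrix = .default_slm_matrix(), ..., seed = seed),
                "lens" = run_lens,
                "cells" = run_cells,
                stop("run_experiment: unknown experiment '", name, "'"))
  res <- fun(..., seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    prov <- list(experiment = name, seed = seed,
                 parameters = lapply(list(...), function(x)
                   if (is.atomic(x)) x else "<object>"),
                 package_version = as.character(utils::packageVersion("gpqpi")),
                 timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (inherits(res, "stability_report") || inherits(res, "accuracy_report"))
      write_report(res, file.path(out_dir, "report.json"))
  }
  res
}

# 5x5 pi-stroke block in a 6x6 lattice (the non-addressed frame is all zero)
.default_slm_matrix <- function() {
  m <- matrix(0, 6, 6)
  m[1:5, 1:5] <- pi
  m
}

#' Generate the canonical small test fixtures
#'
#' Writes one small hologram per experiment class (mirror, SLM, lens,
#' cells) as TIFF + JSON sidecar plus the scene descriptors; byte-identical
#' for identical seeds.
#'
#' @param dir output directory.
#' @param seed integer seed.
#' @return the directory, invisibly.
#' @export
make_fixtures <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- make_spectrum(600, 50, 5)
  scenes <- list(
    mirror = mirror_scene(128, 0.5, dz = 150),
    slm = slm_scene(128, 0.25, pixel_size = 8, phase_matrix = .default_slm_matrix()),
    lens = gp_lens_scene(128, 1, focal_length = 100),
    cells = cell_phantom(128, 0.5, n_cells = 2, radius_range = c(5, 7),
                         seed = seed))
  for (nm in names(scenes)) {
    h <- form_hologram(scenes[[nm]], sp,
                       carrier = if (nm == "slm") c(0.6, 0) else c(0.125, 0),
                       noise = list(photon_budget = 1e4), seed = seed)
    write_hologram_stack(h, file.path(dir, paste0(nm, ".tiff")))
    write_scene_descriptor(scenes[[nm]], file.path(dir, paste0(nm, "_scene.json")))
  }
  invisible(dir)
}
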