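#' Form an achromatic off-axis hologram from a scene
#'
#' The detector intensity is the incoherent superposition over the spectral
#' lines of the two-beam interference pattern of the sample and reference
#' waves, recorded on a carrier whose spatial frequency is identical for
#' every wavelength (the defining property of the achromatic design):
#' \deqn{I(x,y) = \sum_\lambda w_\lambda\big[|s|^2 + |r|^2 +
#'   2|s||r|\cos(2\pi\,\nu_c\cdot(x,y) + \Phi_s - \Phi_r +
#'   2\pi\,\mathrm{OPD}/\lambda)\big].}
#' This is the fully incoherent, ideal point-imaging limit in which
#' retardance restoration from the sideband is exact; an optional Gaussian
#' point-spread blur approximates finite numerical aperture.
#'
#' Noise model (all optional, deterministic given `seed`):
#' \itemize{
#' \item per-frame piston drift, Gaussian in height units (`drift_nm`),
#'   entering the sample arm as \eqn{4\pi\,\delta z/\lambda};
#' \item Poisson shot noise after scaling the mean intensity to
#'   `photon_budget` counts/pixel;
#' \item additive Gaussian read noise `read_sigma`, expressed relative to
#'   the unit-amplitude intensity scale so that a calibrated value
#'   transfers between acquisition geometries.
#' }
#' Negative intensities are clipped to zero.
#'
#' @param scene a `scene_spec`.
#' @param spectrum a `spectrum` (see [make_spectrum()]).
#' @param carrier carrier frequency vector `c(fx, fy)`, cycles/um,
#'   wavelength-independent; must be below Nyquist.
#' @param opd_offset scalar optical-path-difference offset, um (models the
#'   prism compensator; large offsets destroy broadband fringe contrast).
#' @param noise list with any of `drift_nm`, `read_sigma`, `photon_budget`,
#'   `psf_sigma_um`.
#' @param seed integer seed for the noise draws.
#' @param frame frame index stored in the metadata.
#' @return An object of class `hologram`: list with `intensity` (matrix,
#'   >= 0), `pitch`, `carrier`, `spectrum`, `frame`, `meta`.
#' @export
form_hologram <- function(scene, spectrum = make_spectrum(n_samples = 1),
                          carrier = c(0.125, 0), opd_offset = 0,
                          noise = list(), seed = NULL, frame = 1L) {
  stopifnot(inherits(scene, "scene_spec"))
  nyq <- 1 / (2 * scene$pitch)
  if (sqrt(sum(carrier^2)) >= nyq)
    stop(sprintf("form_hologram: carrier magnitude %.4g >= Nyquist %.4g cycles/um (aliasing)",
                 sqrt(sum(carrier^2)), nyq))
  budget <- noise$photon_budget
  if (!is.null(budget) && budget < 0)
    stop("form_hologram: photon budget must be nonnegative")
  if (!is.null(seed)) set.seed(as.integer(seed))
  drift <- if (!is.null(noise$drift_nm) && noise$drift_nm > 0)
    stats::rnorm(1, 0, noise$drift_nm) else 0
  co <- .scene_coords(scene$nx, scene$ny, scene$pitch)
  carrier_phase <- 2 * pi * (carrier[1L] * co$x + carrier[2L] * co$y)
  a_s <- scene$amp_s; a_r <- scene$amp_r
  I <- matrix(0, scene$ny, scene$nx)
  for (k in seq_len(nrow(spectrum))) {
    wl <- spectrum$wavelength[k]        # nm
    w <- spectrum$weight[k]
    dphi <- scene$phi_s(wl) - scene$phi_r(wl) +
      4 * pi * drift / wl +             # piston drift in height units
      2 * pi * opd_offset / (wl / 1000) # OPD offset in um
    I <- I + w * (a_s^2 + a_r^2 + 2 * a_s * a_r * cos(carrier_phase + dphi))
  }
  if (!is.null(noise$psf_sigma_um) && noise$psf_sigma_um > 0)
    I <- .gaussian_blur(I, noise$psf_sigma_um / scene$pitch)
  scale <- 1
  if (!is.null(budget) && budget > 0) {
    scale <- budget / mean(I)
    I <- matrix(stats::rpois(length(I), I * scale), scene$ny, scene$nx)
  }
  if (!is.null(noise$read_sigma) && noise$read_sigma > 0)
    I <- I + stats::rnorm(length(I), 0, noise$read_sigma * scale)
  I[I < 0] <- 0
  structure(list(intensity = I, pitch = scene$pitch, carrier = carrier,
                 spectrum = spectrum, frame = as.integer(frame),
                 meta = list(opd_offset = opd_offset, noise = noise,
                             seed = seed, scale = scale, drift_nm = drift)),
            class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram>  %d x %d px, pitch %.4g um, carrier (%.4g, %.4g) cycles/um, %d spectral line(s), frame %d\n",
              nrow(x$intensity), ncol(x$intensity), x$pitch,
              x$carrier[1L], x$carrier[2L], nrow(x$spectrum), x$frame))
  invisible(x)
}

#' Fringe contrast in a window of a hologram
#'
#' Fits `I ~ a0 + b cos + c sin` at the dominant fringe frequency of the
#' window (found from the FFT peak) and returns the Michelson contrast
#' \eqn{(I_{max}-I_{min})/(I_{max}+I_{min}) = \sqrt{b^2+c^2}/a_0} of the
#' fitted sinusoid.  Diagnostic for coherence gating: with broadband light
#' the contrast collapses once the OPD offset exceeds the coherence length.
#'
#' @param holo a `hologram`.
#' @param window `c(row1, row2, col1, col2)` or NULL for the full frame;
#'   must span at least 3 fringe periods.
#' @return contrast in `[0, 1]`.
#' @export
fringe_contrast <- function(holo, window = NULL) {
  I <- holo$intensity
  if (!is.null(window)) {
    stopifnot(length(window) == 4L)
    I <- I[window[1L]:window[2L], window[3L]:window[4L]]
  }
  nu <- sqrt(sum(holo$carrier^2))
  span <- max(dim(I)) * holo$pitch
  if (nu > 0 && span * nu < 3)
    stop("fringe_contrast: window spans fewer than 3 fringe periods")
  co <- .scene_coords(ncol(I), nrow(I), holo$pitch)
  ph <- 2 * pi * (holo$carrier[1L] * co$x + holo$carrier[2L] * co$y)
  X <- cbind(1, as.vector(cos(ph)), as.vector(sin(ph)))
  cf <- stats::lm.fit(X, as.vector(I))$coefficients
  amp <- sqrt(cf[2L]^2 + cf[3L]^2)
  unname(min(1, amp / cf[1L]))
}

#' Measured fringe period per spectral line
#'
#' Forms a single-line hologram for each wavelength of the spectrum and
#' locates the dominant off-DC FFT peak; for an achromatic carrier every
#' line yields the same period `1/|carrier|` within one FFT bin.
#'
#' @param scene a `scene_spec`.
#' @param spectrum a `spectrum` with >= 2 lines.
#' @param carrier carrier vector, cycles/um.
#' @return data.frame with `wavelength` (nm), `period_um`, `freq_cyc_um`.
#' @export
fringe_period_per_line <- function(scene, spectrum, carrier = c(0.125, 0)) {
  if (nrow(spectrum) < 2L)
    stop("fringe_period_per_line: need at least 2 spectral lines")
  out <- lapply(seq_len(nrow(spectrum)), function(k) {
    mono <- make_spectrum(spectrum$wavelength[k], 0, 1)
    h <- form_hologram(scene, mono, carrier)
    I <- h$intensity - mean(h$intensity)
    F <- stats::fft(I)
    ny <- nrow(I); nx <- ncol(I)
    fx <- .fftfreq(nx, scene$pitch)
    fy <- .fftfreq(ny, scene$pitch)
    P <- Mod(F)^2
    # keep one half-plane to pick a single conjugate peak
    half <- outer(fy, fx, function(a, b) b > 0 | (b == 0 & a > 0))
    P[!half] <- 0
    i <- arrayInd(which.max(P), dim(P))
    f <- sqrt(fx[i[2L]]^2 + fy[i[1L]]^2)
    data.frame(wavelength = spectrum$wavelength[k],
               period_um = 1 / f, freq_cyc_um = f)
  })
  do.call(rbind, out)
}

# FFT frequency axis in cycles/um for n samples at the given pitch
.fftfreq <- function(n, pitch) {
  k <- c(0:(floor((n - 1) / 2)), -(ceiling((n - 1) / 2)):-1)
  k / (n * pitch)
}

#' Write / read hologram stacks as multi-page 16-bit TIFF + JSON sidecar
#'
#' Intensities are scaled by the recorded `scale16` factor into the 16-bit
#' range; reading restores the quantized values exactly, so a written stack
#' round-trips bit-for-bit against its quantized representation.
#'
#' @param holos a `hologram` or list of holograms (common geometry).
#' @param path output TIFF path; the sidecar is written at `<path>.json`.
#' @return `write_hologram_stack()`: the path, invisibly.
#'   `read_hologram_stack()`: list of `hologram` objects.
#' @export
write_hologram_stack <- function(holos, path) {
  if (inherits(holos, "hologram")) holos <- list(holos)
  imax <- max(vapply(holos, function(h) max(h$intensity), 0), 1e-12)
  scale16 <- 65535 / imax
  pages <- lapply(holos, function(h) {
    q <- round(h$intensity * scale16)
    q[q > 65535] <- 65535
    q / 65535   # tiff expects [0,1]; 16-bit storage keeps integers exact
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  h1 <- holos[[1L]]
  side <- list(pitch = h1$pitch, carrier = h1$carrier,
               spectrum = list(wavelength = h1$spectrum$wavelength,
                               weight = h1$spectrum$weight,
                               center = attr(h1$spectrum, "center"),
                               fwhm = attr(h1$spectrum, "fwhm")),
               frames = vapply(holos, function(h) h$frame, 0L),
               scale16 = scale16,
               seeds = lapply(holos, function(h) h$meta$seed))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_hologram_stack
#' @export
read_hologram_stack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sp <- data.frame(wavelength = side$spectrum$wavelength,
                   weight = side$spectrum$weight)
  attr(sp, "center") <- side$spectrum$center
  attr(sp, "fwhm") <- side$spectrum$fwhm
  class(sp) <- c("spectrum", "data.frame")
  lapply(seq_along(pages), function(i) {
    structure(list(intensity = pages[[i]] / side$scale16,
                   pitch = side$pitch, carrier = side$carrier,
                   spectrum = sp, frame = side$frames[i],
                   meta = list(scale16 = side$scale16)),
              class = "hologram")
  })
}
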