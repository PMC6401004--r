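#' Phase map container
#'
#' @param phase matrix of phase values, radians.
#' @param pitch pixel pitch, um.
#' @param wrapped logical: values confined to (-pi, pi].
#' @param meta free-form processing provenance.
#' @return An object of class `phase_map`.
#' @export
phase_map <- function(phase, pitch, wrapped = TRUE, meta = list()) {
  stopifnot(is.matrix(phase))
  structure(list(phase = phase, pitch = pitch, wrapped = isTRUE(wrapped),
                 meta = meta),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("<phase_map%s>  %d x %d px, pitch %.4g um, range [%.3f, %.3f] rad\n",
              if (x$wrapped) " (wrapped)" else " (unwrapped)",
              nrow(x$phase), ncol(x$phase), x$pitch,
              min(x$phase), max(x$phase)))
  invisible(x)
}

# principal value in (-pi, pi]
.wrap <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Sideband demodulation of an off-axis hologram
#'
#' Standard single-shot Fourier demodulation: the hologram is apodized with
#' a Tukey window (alpha = 0.1), multiplied by `exp(-2*pi*i nu_c . (x,y))`
#' to bring the +1 sideband to baseband, Fourier transformed, low-pass
#' filtered with a circular mask of radius `bandwidth`, and inverse
#' transformed.  The argument of the returned complex field is the wrapped
#' retardance estimate.  The conjugate (-1) sideband corresponds to the
#' carrier with the opposite sign; the +1 order at the configured carrier
#' is used throughout.
#'
#' @param holo a `hologram`.
#' @param carrier carrier vector, cycles/um (defaults to the hologram's).
#' @param bandwidth low-pass radius, cycles/um; default half the carrier
#'   magnitude (the widest radius that is always separable).
#' @param taper `"hard"` for a sharp circular mask, `"gaussian"` for a
#'   Gaussian mask of standard deviation `bandwidth/2` (negligible sidelobe
#'   ringing; preferred when the scene contains sharp phase steps).
#' @param apodize apply the Tukey window before transforming.
#' @return An object of class `complex_field`: list with `field` (complex
#'   matrix), `pitch`, `meta`.
#' @export
demodulate <- function(holo, carrier = NULL, bandwidth = NULL,
                       taper = c("hard", "gaussian"), apodize = TRUE) {
  stopifnot(inherits(holo, "hologram"))
  taper <- match.arg(taper)
  if (is.null(carrier)) carrier <- holo$carrier
  ncar <- sqrt(sum(carrier^2))
  if (is.null(bandwidth)) bandwidth <- ncar / 2
  if (ncar < 2 * bandwidth)
    stop(sprintf(paste0("demodulate: sideband/DC overlap: sideband radius %.4g",
                        " around the carrier at %.4g intersects the DC band of",
                        " radius %.4g (cycles/um)"),
                 bandwidth, ncar, bandwidth))
  I <- holo$intensity
  I <- I - mean(I)   # suppress the zero-order term before windowing
  ny <- nrow(I); nx <- ncol(I)
  if (apodize) I <- I * outer(.tukey_px(ny, 16L), .tukey_px(nx, 16L))
  co <- .scene_coords(nx, ny, holo$pitch)
  g <- I * exp(-2i * pi * (carrier[1L] * co$x + carrier[2L] * co$y))
  G <- stats::fft(g)
  fx <- .fftfreq(nx, holo$pitch)
  fy <- .fftfreq(ny, holo$pitch)
  d2 <- outer(fy^2, fx^2, `+`)
  mask <- if (taper == "hard") {
    (d2 <= bandwidth^2) * 1
  } else {
    exp(-d2 / (2 * (bandwidth / 2)^2))
  }
  field <- stats::fft(G * mask, inverse = TRUE) / length(G)
  structure(list(field = field, pitch = holo$pitch,
                 meta = list(carrier = carrier, bandwidth = bandwidth,
                             taper = taper, apodize = apodize)),
            class = "complex_field")
}

# Tukey window with a fixed taper width in pixels per side (the apodized
# margin matches the 16-px border excluded from quantitative comparisons)
.tukey_px <- function(n, width = 16L) {
  width <- min(width, floor((n - 1) / 2))
  w <- rep(1, n)
  t <- seq_len(width)
  ramp <- 0.5 * (1 - cos(pi * (t - 1) / width))
  w[t] <- ramp
  w[n + 1L - t] <- ramp
  w
}

#' Wrapped phase of a complex field
#'
#' Element-wise argument in (-pi, pi].  Zero-amplitude pixels get phase 0
#' and are flagged in the low-quality mask stored in `meta$low_quality`.
#'
#' @param field a `complex_field`.
#' @return A wrapped `phase_map`.
#' @export
wrapped_phase <- function(field) {
  stopifnot(inherits(field, "complex_field"))
  ph <- Arg(field$field)
  lowq <- Mod(field$field) == 0
  ph[lowq] <- 0
  phase_map(ph, field$pitch, wrapped = TRUE,
            meta = c(field$meta, list(low_quality = lowq,
                                      amplitude = Mod(field$field))))
}

#' Background compensation of a phase map
#'
#' Either subtracts a stored reference phase map (wrapped arithmetic when
#' both maps are wrapped — the non-addressed-device calibration) or removes
#' a fitted low-order 2-D polynomial (default order 1: piston + tilt).
#'
#' @param phase a `phase_map`.
#' @param reference a reference `phase_map` on the same grid, or NULL.
#' @param poly_order polynomial order to remove when `reference` is NULL.
#' @param mask optional logical matrix restricting the polynomial fit.
#' @return A `phase_map`.
#' @export
subtract_background <- function(phase, reference = NULL, poly_order = 1,
                                mask = NULL) {
  stopifnot(inherits(phase, "phase_map"))
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "phase_map"))
    if (!all(dim(phase$phase) == dim(reference$phase)))
      stop("subtract_background: grid mismatch between phase and reference")
    d <- phase$phase - reference$phase
    if (phase$wrapped || reference$wrapped) d <- .wrap(d)
    return(phase_map(d, phase$pitch, wrapped = phase$wrapped || reference$wrapped,
                     meta = c(phase$meta, list(background = "reference"))))
  }
  p <- phase$phase
  ny <- nrow(p); nx <- ncol(p)
  co <- .scene_coords(nx, ny, phase$pitch)
  sel <- if (is.null(mask)) rep(TRUE, length(p)) else as.vector(mask)
  X <- .poly_basis(co$x, co$y, poly_order)
  cf <- stats::lm.fit(X[sel, , drop = FALSE], as.vector(p)[sel])$coefficients
  cf[is.na(cf)] <- 0
  fit <- matrix(X %*% cf, ny, nx)
  phase_map(p - fit, phase$pitch, wrapped = FALSE,
            meta = c(phase$meta, list(background = sprintf("poly:%d", poly_order))))
}

.poly_basis <- function(x, y, order) {
  terms <- list(rep(1, length(x)))
  for (d in seq_len(order))
    for (i in 0:d)
      terms[[length(terms) + 1L]] <- as.vector(x)^(d - i) * as.vector(y)^i
  do.call(cbind, terms)
}

#' Two-dimensional phase unwrapping
#'
#' Transform-based (unweighted) least-squares unwrapping: the wrapped
#' Laplacian of the input is computed from wrapped first differences and
#' the discrete Poisson equation is solved under Neumann boundary
#' conditions by even mirror extension and FFT.  For noiseless smooth
#' inputs whose true neighbor differences stay below pi (e.g. the
#' quadratic phase of the f = 100 mm lens) the result equals the true phase
#' up to a global constant to numerical precision.  With
#' `congruent = TRUE` (default) the smooth least-squares surface is snapped
#' back to the measured values modulo 2*pi, which preserves the
#' least-squares estimate of the wrap counts while retaining the measured
#' per-pixel detail.  The number of phase residues (inconsistencies of the
#' wrapped gradient field) is reported in `meta$n_residues`; the
#' least-squares solution degrades gracefully in their presence.
#'
#' @param phase a wrapped `phase_map`.
#' @param congruent snap the solution to the input modulo 2*pi.
#' @return An unwrapped `phase_map`.
#' @export
unwrap <- function(phase, congruent = TRUE) {
  stopifnot(inherits(phase, "phase_map"))
  psi <- phase$phase
  ny <- nrow(psi); nx <- ncol(psi)
  dx <- .wrap(psi[, -1L, drop = FALSE] - psi[, -nx, drop = FALSE])
  dy <- .wrap(psi[-1L, , drop = FALSE] - psi[-ny, , drop = FALSE])
  # residues: circulation of wrapped gradients around elementary loops
  if (ny > 1L && nx > 1L) {
    circ <- dx[-ny, , drop = FALSE] + dy[, -1L, drop = FALSE] -
      dx[-1L, , drop = FALSE] - dy[, -nx, drop = FALSE]
    n_res <- sum(abs(circ) > pi)
  } else n_res <- 0L
  rho <- matrix(0, ny, nx)
  rho[, -nx] <- rho[, -nx] + dx
  rho[, -1L] <- rho[, -1L] - dx
  rho[-ny, ] <- rho[-ny, ] + dy
  rho[-1L, ] <- rho[-1L, ] - dy
  u <- .poisson_neumann(rho)
  if (congruent) u <- psi + 2 * pi * round((u - psi) / (2 * pi))
  phase_map(u, phase$pitch, wrapped = FALSE,
            meta = c(phase$meta, list(n_residues = n_res,
                                      unwrap = "lsq-fft",
                                      congruent = congruent)))
}

# solve the 5-point discrete Poisson equation  Lap(u) = rho  with Neumann
# boundaries via even mirror extension and the periodic FFT eigenvalues
.poisson_neumann <- function(rho) {
  ny <- nrow(rho); nx <- ncol(rho)
  E <- rbind(cbind(rho, rho[, nx:1]), cbind(rho[ny:1, ], rho[ny:1, nx:1]))
  F <- stats::fft(E)
  p <- 2 * cos(pi * (0:(2 * ny - 1)) / ny)
  q <- 2 * cos(pi * (0:(2 * nx - 1)) / nx)
  D <- outer(p, q, `+`) - 4
  D[1L, 1L] <- 1
  F <- F / D
  F[1L, 1L] <- 0
  U <- Re(stats::fft(F, inverse = TRUE)) / length(F)
  U[seq_len(ny), seq_len(nx)]
}

#' One-dimensional Itoh unwrapping
#'
#' Cumulative sum of wrapped first differences; exact whenever the true
#' sample-to-sample increments stay below pi.  Used for piston time series
#' (e.g. the piezo staircase) and as the oracle for the 2-D unwrapper.
#'
#' @param x vector of wrapped phases, radians.
#' @return unwrapped vector anchored at `x[1]`.
#' @export
unwrap_1d <- function(x) {
  if (length(x) < 2L) return(x)
  x[1L] + c(0, cumsum(.wrap(diff(x))))
}

#' Robust piston estimate of a phase map
#'
#' Circular mean `Arg(mean(exp(i*phi)))` over the interior of the map
#' (default border of 16 px excluded), immune to wrapping of the piston
#' value itself.
#'
#' @param phase a `phase_map` (wrapped or not).
#' @param border border width to exclude, px.
#' @return scalar phase in (-pi, pi].
#' @export
piston_phase <- function(phase, border = 16L) {
  p <- phase$phase
  ny <- nrow(p); nx <- ncol(p)
  b <- min(border, floor((min(ny, nx) - 1) / 2))
  sel <- p[(b + 1L):(ny - b), (b + 1L):(nx - b)]
  Arg(mean(exp(1i * sel)))
}

#' Full retardance reconstruction from a hologram
#'
#' Convenience chain: demodulate, take the wrapped phase, optionally
#' subtract a background (reference map or polynomial), optionally unwrap.
#'
#' @param holo a `hologram`.
#' @param carrier,bandwidth,taper passed to [demodulate()].
#' @param background NULL, a reference `phase_map`, or an integer
#'   polynomial order.
#' @param do_unwrap unwrap the result.
#' @return A `phase_map`.
#' @export
reconstruct_phase <- function(holo, carrier = NULL, bandwidth = NULL,
                              taper = "hard", background = NULL,
                              do_unwrap = FALSE, apodize = TRUE) {
  pm <- wrapped_phase(demodulate(holo, carrier, bandwidth, taper, apodize))
  if (do_unwrap) pm <- unwrap(pm)
  if (!is.null(background)) {
    pm <- if (inherits(background, "phase_map"))
      subtract_background(pm, reference = background)
    else subtract_background(pm, poly_order = as.integer(background))
  }
  pm
}

#' Write / read phase maps as 32-bit float TIFF + JSON sidecar
#'
#' @param phase a `phase_map`.
#' @param path output TIFF path; sidecar at `<path>.json`.
#' @export
write_phase_map <- function(phase, path) {
  stopifnot(inherits(phase, "phase_map"))
  rng <- range(phase$phase)
  scale <- max(rng[2L] - rng[1L], .Machine$double.eps)
  tiff::writeTIFF((phase$phase - rng[1L]) / scale, path,
                  bits.per.sample = 32L, compression = "none", reduce = FALSE)
  side <- list(pitch = phase$pitch, wrapped = phase$wrapped,
               offset = rng[1L], scale = scale,
               provenance = phase$meta[setdiff(names(phase$meta),
                                               c("low_quality", "amplitude"))])
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_phase_map
#' @export
read_phase_map <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path)
  phase_map(m * side$scale + side$offset, side$pitch, wrapped = side$wrapped,
            meta = list(provenance = side$provenance))
}
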