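#' Jones calculus in the circular polarization basis
#'
#' The polarization-coded optical train is modeled with Jones vectors in the
#' circular basis \eqn{(e_L, e_R)}: `e_L` is the complex amplitude of the
#' left-handed and `e_R` of the right-handed circular component.  The
#' handedness convention is fixed once for the whole package: LHCP is the
#' state \eqn{(\hat{x} + i\hat{y})/\sqrt{2}} seen from the receiver, so the
#' circular components are obtained from the linear (x, y) components by
#' \deqn{e_L = (E_x - iE_y)/\sqrt{2}, \quad e_R = (E_x + iE_y)/\sqrt{2}.}
#' All handedness statements elsewhere in the package are relative to this
#' convention.
#'
#' @param e_L,e_R complex amplitudes of the circular components.
#' @return An object of class `jones_vector`.
#' @examples
#' v <- jones_vector(1, 0)   # pure LHCP
#' jones_intensity(v)
#' @export
jones_vector <- function(e_L, e_R) {
  stopifnot(length(e_L) == 1L, length(e_R) == 1L)
  v <- c(as.complex(e_L), as.complex(e_R))
  if (any(!is.finite(Re(v))) || any(!is.finite(Im(v))))
    stop("jones_vector: amplitudes must be finite")
  structure(v, class = "jones_vector")
}

#' @rdname jones_vector
#' @param v a `jones_vector`.
#' @export
jones_intensity <- function(v) {
  sum(Mod(unclass(v))^2)
}

#' Construct a Jones operator (2x2 complex matrix, circular basis)
#'
#' @param m 2x2 complex matrix acting on `(e_L, e_R)`.
#' @return An object of class `jones_operator`.
#' @export
jones_operator <- function(m) {
  m <- matrix(as.complex(m), 2L, 2L)
  if (any(!is.finite(Re(m))) || any(!is.finite(Im(m))))
    stop("jones_operator: matrix entries must be finite")
  structure(m, class = c("jones_operator", "matrix"))
}

#' Apply a Jones operator to a Jones vector
#' @param op a `jones_operator`.
#' @param v a `jones_vector`.
#' @export
jones_apply <- function(op, v) {
  out <- unclass(op) %*% unclass(v)
  jones_vector(out[1L], out[2L])
}

# basis change (E_x, E_y) -> (e_L, e_R) for the package convention
.circ_from_lin <- matrix(c(1, 1, -1i, 1i), 2L, 2L) / sqrt(2)

.lin_to_circ <- function(m_lin) {
  T <- .circ_from_lin
  T %*% m_lin %*% solve(T)
}

#' Geometric-phase grating operator
#'
#' A half-wave-like geometric-phase element with local anisotropy-axis
#' orientation `phi` swaps the circular handedness and imprints the
#' geometric (Pancharatnam-Berry) phase \eqn{\pm 2\phi}: a pure LHCP input
#' emerges RHCP with phase factor \eqn{e^{+i2\phi}}, a pure RHCP input
#' emerges LHCP with \eqn{e^{-i2\phi}}.  The operator is unitary: the
#' element is modeled as lossless.
#'
#' @param phi local anisotropy-axis orientation in radians.
#' @return A `jones_operator`.
#' @examples
#' op <- gpg_operator(pi / 4)
#' jones_apply(op, jones_vector(1, 0))   # RHCP with phase +pi/2
#' @export
gpg_operator <- function(phi) {
  if (length(phi) != 1L || !is.finite(phi))
    stop("gpg_operator: phi must be a single finite number")
  jones_operator(matrix(c(0, exp(2i * phi), exp(-2i * phi), 0), 2L, 2L))
}

#' Linear retarder (waveplate) operator
#'
#' Retarder with retardance `retardance` between fast and slow axes and fast
#' axis at `azimuth` from the x axis, expressed in the circular basis.  A
#' quarter-wave plate (`retardance = pi/2`) at 45 degrees converts
#' horizontal/vertical linear polarization into pure circular states (up to
#' a global phase), which is how the instrument prepares the LHCP/RHCP
#' sample and reference waves.
#'
#' @param retardance retardance in radians.
#' @param azimuth fast-axis azimuth in radians.
#' @return A `jones_operator`.
#' @export
waveplate_operator <- function(retardance, azimuth = 0) {
  d <- retardance / 2
  rot <- matrix(c(cos(azimuth), sin(azimuth), -sin(azimuth), cos(azimuth)), 2L, 2L)
  core <- diag(c(exp(-1i * d), exp(1i * d)))
  m_lin <- rot %*% core %*% t(rot)
  jones_operator(.lin_to_circ(m_lin))
}

#' Linear analyzer (polarizer) operator
#'
#' Projects both circular components onto the linear state at `angle`,
#' allowing them to interfere on the detector.  For equal-amplitude circular
#' components with relative phase \eqn{\delta} the transmitted intensity is
#' proportional to \eqn{1 + \cos(\delta + c)} where the offset `c` depends
#' only on the analyzer angle.  The operator is a rank-1 projector.
#'
#' @param angle transmission-axis angle in radians.
#' @return A `jones_operator`.
#' @export
analyzer_operator <- function(angle = 0) {
  c2 <- cos(angle)^2
  s2 <- sin(angle)^2
  cs <- cos(angle) * sin(angle)
  m_lin <- matrix(c(c2, cs, cs, s2), 2L, 2L)
  jones_operator(.lin_to_circ(m_lin))
}

#' Ideal-mirror operator
#'
#' Metallic mirror modeled as a pure handedness swap with no added phase;
#' real mirror phase shifts are absorbed into the background phase.
#'
#' @return A `jones_operator`.
#' @export
mirror_operator <- function() {
  jones_operator(matrix(c(0, 1, 1, 0), 2L, 2L))
}

#' Diffraction angles of the geometric-phase grating
#'
#' First-order deflection of a phase grating whose geometric phase completes
#' one 2*pi ramp over the spatial period `period_phase`.  LHCP and RHCP are
#' sent into opposite orders, so their mutual angle is twice the first-order
#' angle.  Note that `period_phase` is the period of the *phase* ramp; for a
#' half-wave geometric-phase grating with anisotropy-axis period
#' \eqn{\Lambda_{axis}} the phase \eqn{2\phi} ramps with period
#' \eqn{\Lambda_{axis}} only when one full axis rotation spans 2*pi of
#' phase per ramp as manufactured.  The parameter is exposed explicitly so
#' either reading can be used.
#'
#' @param period_phase spatial period of one 2*pi geometric-phase ramp, um.
#' @param wavelength wavelength, um.
#' @return list with `order_angle` and `mutual_angle`, both in degrees.
#' @examples
#' grating_deflection(9, 0.6)$mutual_angle  # ~7.65, rounds to 8 degrees
#' @export
grating_deflection <- function(period_phase, wavelength) {
  stopifnot(length(period_phase) == 1L, length(wavelength) == 1L)
  if (!is.finite(period_phase) || !is.finite(wavelength) ||
      period_phase <= 0 || wavelength <= 0)
    stop("grating_deflection: period and wavelength must be positive and finite")
  if (wavelength >= period_phase)
    stop("grating_deflection: no propagating first order (wavelength >= period)")
  a <- asin(wavelength / period_phase) * 180 / pi
  list(order_angle = a, mutual_angle = 2 * a)
}
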