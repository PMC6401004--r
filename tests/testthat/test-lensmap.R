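quad_phase <- function(n, pitch, f_mm, wl_nm = 600) {
  sc <- gp_lens_scene(n, pitch, f_mm, design_wavelength = wl_nm)
  phase_map(sc$truth$single_pass_phase, pitch, wrapped = FALSE)
}

test_that("single-pass phase halves the retardance and stays linear", {
  p <- quad_phase(64, 4, 100)
  ret <- phase_map(2 * p$phase, 4, wrapped = FALSE)
  expect_equal(single_pass_phase(ret)$phase, p$phase)
  expect_equal(single_pass_phase(phase_map(matrix(0, 8, 8), 1, FALSE))$phase,
               matrix(0, 8, 8))
  wrapped <- phase_map(matrix(0.1, 8, 8), 1, wrapped = TRUE)
  expect_error(single_pass_phase(wrapped), "wrap")
})

test_that("focal-length fitting inverts the quadratic phase model", {
  p <- quad_phase(256, 500 / 256, 100)
  ft <- fit_focal_length(p, 600)
  expect_equal(ft$f_mm, 100, tolerance = 1e-3)
  expect_lt(ft$rms_residual, 1e-6)

  # phase scaled by 2 halves the focal length
  p2 <- phase_map(2 * p$phase, p$pitch, wrapped = FALSE)
  expect_equal(fit_focal_length(p2, 600)$f_mm, 50, tolerance = 1e-3)

  flat <- phase_map(matrix(1.3, 64, 64), 1, wrapped = FALSE)
  expect_error(fit_focal_length(flat, 600), "degenerate")
})

test_that("Fresnel number follows a^2/(lambda f)", {
  expect_equal(round(fresnel_number(0.25, 600, 100)), 1)
  expect_equal(fresnel_number(0.25, 600, 100), 0.0625 / 0.06, tolerance = 1e-12)
  expect_equal(fresnel_number(0.5, 600, 100), 4 * fresnel_number(0.25, 600, 100))
  expect_equal(fresnel_number(0.25, 600, 200), 0.52, tolerance = 1e-2)
  expect_error(fresnel_number(-1, 600, 100), "positive")
})

# slow independent oracle: direct radial Fresnel quadrature for the on-axis
# field of a circularly symmetric aperture/lens
fresnel_axial_direct <- function(z_mm, a_mm, f_mm = Inf, wl_nm = 600,
                                 n_r = 4000) {
  lam <- wl_nm / 1000; z <- z_mm * 1000; a <- a_mm * 1000; f <- f_mm * 1000
  r <- seq(0, a, length.out = n_r + 1)[-1] - a / n_r / 2
  vapply(z, function(zz) {
    ph <- pi * r^2 / lam * (1 / zz - 1 / f)
    Mod(sum(exp(1i * ph) * r) * (a / n_r) / (lam * zz))^2
  }, 0)
}

test_that("the closed-form Fresnel axial intensity matches direct quadrature", {
  z <- seq(30, 300, by = 2.5)
  direct <- fresnel_axial_direct(z, 0.25, 100)
  closed <- analytic_axial_intensity(z, 0.25, 100, 600)
  expect_equal(closed / max(closed), direct / max(direct), tolerance = 1e-6)

  # I(z = f) = 1 under the chosen normalization
  expect_equal(analytic_axial_intensity(100, 0.25, 100, 600), 1)

  # zeros where 1/z - 1/f = 2 m lambda / a^2 (hand solution: z ~ 34.2 mm)
  z1 <- 1 / (1 / 100 + 2 * 600e-6 / 0.25^2)
  expect_lt(analytic_axial_intensity(z1, 0.25, 100, 600), 1e-20)
  expect_error(analytic_axial_intensity(-3, 0.25, 100), "positive")
})

test_that("propagation kernels reproduce the direct Fresnel oracle", {
  # direct Rayleigh-Sommerfeld summation vs radial quadrature of the ideal
  # open circular aperture (flat phase, on-axis Fresnel oscillations)
  n <- 64; pitch <- 8
  flat <- phase_map(matrix(0, n, n), pitch, wrapped = FALSE)
  co <- (seq_len(n) - 1 - (n - 1) / 2) * pitch
  # area-weighted (anti-aliased) disk of radius 0.2 mm: the oracle below
  # integrates the continuous disk, so edge pixels carry coverage weights
  ss <- 8
  fine <- ((1:(n * ss)) - 1 - (n * ss - 1) / 2) * pitch / ss
  fm <- outer(fine^2, fine^2, `+`) <= 200^2
  mask <- matrix(0, n, n)
  for (i in 1:ss) for (j in 1:ss)
    mask <- mask + fm[seq(i, n * ss, ss), seq(j, n * ss, ss)]
  mask <- mask / ss^2
  z <- c(40, 60, 90, 140)
  vol <- propagate(flat, 600, z, aperture_mask = mask, on_axis_only = TRUE,
                   method = "direct")
  num <- Mod(vol$on_axis)^2
  direct <- fresnel_axial_direct(z, 0.2, Inf)
  expect_equal(num / max(num), direct / max(direct), tolerance = 0.01)

  # angular spectrum vs discrete Fresnel sum for a smooth-edged (apodized)
  # aperture: FFT propagation is accurate for band-limited fields
  r <- sqrt(outer(co^2, co^2, `+`))
  soft <- 0.5 * (1 - tanh((r - 180) / 40))
  vol_as <- propagate(flat, 600, z, aperture_mask = soft, pad_factor = 4,
                      on_axis_only = TRUE)
  num_as <- Mod(vol_as$on_axis)^2
  lam <- 0.6
  ref <- vapply(z * 1000, function(zz) {
    Mod(sum(soft * exp(1i * pi * r^2 / (lam * zz))) * pitch^2 / (lam * zz))^2
  }, 0)
  expect_equal(num_as / max(num_as), ref / max(ref), tolerance = 0.01)

  expect_error(propagate(flat, 600, 50, method = "direct"), "on_axis_only")
})

test_that("energy is conserved across propagation planes", {
  # short distances: the focused beam stays inside the cropped window
  n <- 64
  p <- quad_phase(n, 8, 100)
  co <- (seq_len(n) - 1 - (n - 1) / 2) * 8
  mask <- outer(co^2, co^2, `+`) <= 150^2
  # pad_factor 1: the returned plane is the whole (periodic) computational
  # domain, so Parseval applies to it directly
  # short distances where the anti-aliasing band limit stays above Nyquist
  vol <- propagate(p, 600, c(1, 3, 6), aperture_mask = mask,
                   pad_factor = 1)
  e0 <- sum(mask)
  for (pl in vol$planes) {
    expect_equal(sum(Mod(pl)^2) / e0, 1, tolerance = 0.02)
  }
})

test_that("a unit-Fresnel-number lens focuses short of the paraxial plane", {
  n <- 256; pitch <- 500 / n
  p <- quad_phase(n, pitch, 100)
  ch <- lens_characterize(phase_map(2 * p$phase, pitch, FALSE),
                          wavelength = 600, aperture_halfwidth = 0.25,
                          z_mm = seq(30, 300, by = 0.5))
  expect_equal(ch$f_mm, 100, tolerance = 1e-3)
  expect_equal(round(ch$fresnel_number), 1)

  z_peak <- ch$z_mm[which.max(ch$axial_intensity)]
  expect_lt(z_peak, 100)

  # numerical and analytic profiles agree: peak and first zero within one
  # axial step, profile correlation > 0.99
  z_peak_th <- ch$z_mm[which.max(ch$axial_intensity_analytic)]
  expect_lte(abs(z_peak - z_peak_th), 0.5)
  first_zero <- function(v, z) z[which.min(v)]
  nearz <- ch$z_mm < 60
  expect_lte(abs(first_zero(ch$axial_intensity[nearz], ch$z_mm[nearz]) -
                   first_zero(ch$axial_intensity_analytic[nearz], ch$z_mm[nearz])),
             0.5)
  expect_gt(stats::cor(ch$axial_intensity, ch$axial_intensity_analytic), 0.99)

  # asymmetry around the paraxial focus: I(f - dz) > I(f + dz)
  i_lo <- ch$axial_intensity[which.min(abs(ch$z_mm - 85))]
  i_hi <- ch$axial_intensity[which.min(abs(ch$z_mm - 115))]
  expect_gt(i_lo, i_hi)
})
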