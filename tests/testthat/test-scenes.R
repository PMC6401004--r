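test_that("spectrum sampling is normalized, symmetric and has the right coherence length", {
  s1 <- make_spectrum(600, 50, 1)
  expect_equal(s1$wavelength, 600)
  expect_equal(s1$weight, 1)

  s <- make_spectrum(600, 50, 21)
  expect_equal(sum(s$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(s$wavelength) > 0))
  expect_equal(s$weight, rev(s$weight), tolerance = 1e-12)
  expect_equal(s$wavelength + rev(s$wavelength), rep(1200, 21), tolerance = 1e-9)

  expect_equal(coherence_length(s), 7.2)        # 600^2/50 nm = 7.2 um
  expect_identical(coherence_length(s1), Inf)
  expect_error(make_spectrum(-1, 50, 5), "positive")
  expect_error(make_spectrum(600, 50, 0), ">= 1")
})

test_that("mirror scene encodes the double-pass piston 4*pi*dz/lambda", {
  expect_equal(max(abs(scene_retardance(mirror_scene(16, 0.5, 0), 600))), 0)
  expect_equal(scene_retardance(mirror_scene(16, 0.5, 150), 600)[1, 1], pi)
  expect_equal(scene_retardance(mirror_scene(16, 0.5, 300), 600)[1, 1], 2 * pi)
  expect_equal(wrap_pv(scene_retardance(mirror_scene(16, 0.5, 300), 600)[1, 1]),
               wrap_pv(0))

  # exact linearity in dz at fixed wavelength
  r1 <- scene_retardance(mirror_scene(16, 0.5, 100), 600)[1, 1]
  r7 <- scene_retardance(mirror_scene(16, 0.5, 700), 600)[1, 1]
  expect_equal(r7, 7 * r1, tolerance = 1e-12)
  expect_error(mirror_scene(16, 0.5, 1500), "1000")
})

test_that("SLM scene programs piecewise-constant per-pixel phase", {
  m0 <- matrix(0, 5, 5)
  sc0 <- slm_scene(128, 0.25, pixel_size = 5, phase_matrix = m0)
  expect_equal(max(abs(scene_retardance(sc0, 600))), 0)

  m <- matrix(0, 7, 7); m[2:6, 2:6] <- pi   # the pi-stroke 5x5 block
  sc <- slm_scene(256, 0.25, pixel_size = 5, phase_matrix = m,
                  crosstalk_sigma = 0)
  ph <- scene_retardance(sc, 600)
  expect_setequal(unique(as.vector(ph)), c(0, pi))
  # exactly 25 SLM pixels at pi: the programmed area is 25 * (5 um)^2
  expect_equal(sum(ph == pi) * 0.25^2, 25 * 25, tolerance = 0.05)
  # wavelength independence (retardance programming)
  expect_identical(ph, scene_retardance(sc, 550))

  m2 <- matrix(0, 3, 3); m2[2, 2] <- 3.09; m2[2, 3] <- 2.85
  sc2 <- slm_scene(256, 0.25, pixel_size = 5, phase_matrix = m2)
  expect_equal(sc2$truth$phase_matrix[2, 2], 3.09)
  expect_equal(sc2$truth$phase_matrix[2, 3], 2.85)
  expect_error(slm_scene(64, 0.5, pixel_size = 0.25, phase_matrix = m0),
               "pixel_size")
  expect_error(slm_scene(64, 0.5, pixel_size = 5, phase_matrix = matrix(NaN)),
               "finite")
})

test_that("geometric-phase lens scene carries the quadratic single-pass phase", {
  sc <- gp_lens_scene(64, 500 / 64, focal_length = 100, design_wavelength = 600)
  phi <- sc$truth$single_pass_phase
  n <- 64
  cen <- (n + 1) / 2   # origin between pixels for even grids
  expect_equal(phi[32, 32], -pi * ((32 - cen)^2 + (32 - cen)^2) *
                 (500 / 64)^2 / (0.6 * 1e5))

  # hand value: r = 0.25 mm, f = 100 mm, lambda = 600 nm -> -3.27 rad
  r_um <- 250
  expect_equal(-pi * r_um^2 / (0.6 * 1e5), -3.2725, tolerance = 1e-4)

  # retardance = 2*phi by construction, achromatic
  expect_equal(scene_retardance(sc, 600), 2 * phi)
  expect_identical(scene_retardance(sc, 575), scene_retardance(sc, 625))

  # rotational symmetry about the optical axis: quadrant flips agree
  ret <- scene_retardance(sc, 600)
  expect_equal(ret, ret[n:1, ], tolerance = 1e-12)
  expect_equal(ret, t(ret), tolerance = 1e-12)
  expect_error(gp_lens_scene(64, 1, focal_length = 0), "nonzero")
})

test_that("cell phantom conserves mass, is deterministic, and inverts Davies exactly", {
  sc <- cell_phantom(192, 0.5, n_cells = 1, total_mass_range = c(200, 200),
                     seed = 5)
  expect_equal(sum(sc$truth$density) * 0.5^2, 200, tolerance = 200 * 1e-3)

  sc2 <- cell_phantom(192, 0.5, n_cells = 1, total_mass_range = c(200, 200),
                      seed = 5)
  expect_identical(sc$truth$density, sc2$truth$density)

  # round trip: recomputing the phase from the density map matches the scene
  phi <- drymass_to_phase(sc$truth$density, 600, 0.18, 2)
  expect_lt(max(abs(phi - sc$phi_s(600))), 1e-9)

  # scenes never emit NaN
  expect_true(all(is.finite(sc$phi_s(600))), all(is.finite(sc$phi_r(600))))
  expect_error(cell_phantom(64, 0.5, n_cells = 40, seed = 1), "non-overlapping")
})
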