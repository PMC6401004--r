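test_that("monochromatic flat-scene hologram matches the two-beam closed form", {
  sc <- mirror_scene(128, 0.5, 0)
  h <- form_hologram(sc, mono600, carrier = c(0.125, 0))
  co_x <- (seq_len(128) - 1 - 127 / 2) * 0.5
  expect_lt(max(abs(sweep(h$intensity, 2, 2 * (1 + cos(2 * pi * 0.125 * co_x))))),
            1e-12)
  expect_equal(fringe_contrast(h), 1, tolerance = 1e-6)
  expect_true(all(h$intensity >= 0))
})

test_that("a 150 nm mirror step shifts the fringes by half a period", {
  h0 <- form_hologram(mirror_scene(128, 0.5, 0), mono600, c(0.125, 0))
  h1 <- form_hologram(mirror_scene(128, 0.5, 150), mono600, c(0.125, 0))
  # phase pi: I0 + I1 = 4 everywhere (fringes in exact antiphase)
  expect_equal(max(abs(h0$intensity + h1$intensity - 4)), 0, tolerance = 1e-10)
})

test_that("broadband fringe contrast collapses beyond the coherence length", {
  spb <- make_spectrum(600, 50, 21)
  expect_equal(coherence_length(spb), 7.2)
  h_far <- form_hologram(mirror_scene(128, 0.5, 0), spb, c(0.125, 0),
                         opd_offset = 20)
  h_near <- form_hologram(mirror_scene(128, 0.5, 0), spb, c(0.125, 0),
                          opd_offset = 0)
  expect_lt(fringe_contrast(h_far), 0.1)
  expect_gt(fringe_contrast(h_near), 0.99)

  # brute-force spectral-sum oracle for the complex degree of coherence
  gamma <- function(opd_um) {
    Mod(sum(spb$weight * exp(2i * pi * opd_um / (spb$wavelength / 1000))))
  }
  expect_equal(fringe_contrast(h_far), gamma(20), tolerance = 1e-3)
  expect_equal(fringe_contrast(h_near), gamma(0), tolerance = 1e-3)
})

test_that("fringe contrast follows the two-beam amplitude formula", {
  sc <- mirror_scene(128, 0.5, 0)
  sc$amp_r <- 0.5
  h <- form_hologram(sc, mono600, c(0.125, 0))
  expect_equal(fringe_contrast(h), 2 * 0.5 / (1 + 0.25), tolerance = 1e-6)

  sc$amp_r <- 0
  expect_equal(fringe_contrast(form_hologram(sc, mono600, c(0.125, 0))), 0,
               tolerance = 1e-9)
  expect_error(fringe_contrast(h, window = c(1, 8, 1, 8)), "3 fringe periods")
})

test_that("the carrier is achromatic: one fringe period for every spectral line", {
  sc <- mirror_scene(256, 0.5, 0)
  sp3 <- make_spectrum(600, 50, 3)
  sp3$wavelength <- c(575, 600, 625)
  per <- fringe_period_per_line(sc, sp3, carrier = c(0.1, 0))
  bin <- 1 / (256 * 0.5)
  expect_true(all(abs(per$freq_cyc_um - 0.1) <= bin))
  expect_true(all(abs(per$period_um - 10) < 1))
  expect_equal(length(unique(per$period_um)), 1L)  # identical across lines

  per2 <- fringe_period_per_line(sc, sp3, carrier = c(0.2, 0))
  expect_equal(per2$period_um, per$period_um / 2, tolerance = 1e-6)

  # period independent of smooth scene phase content
  scl <- gp_lens_scene(256, 0.5, 1000, aperture_halfwidth = Inf)
  per3 <- fringe_period_per_line(scl, sp3, carrier = c(0.1, 0))
  expect_true(all(abs(per3$freq_cyc_um - 0.1) <= bin))
  expect_error(fringe_period_per_line(sc, mono600, c(0.1, 0)), "2 spectral")
})

test_that("hologram noise model is seeded, Poissonian, and mean-preserving", {
  sc <- mirror_scene(256, 0.5, 0)
  # noiseless mean equals sum of beam intensities within 0.5%
  h <- form_hologram(sc, band600, c(0.35, 0))
  expect_equal(mean(h$intensity), 2, tolerance = 5e-3)

  h1 <- form_hologram(sc, band600, c(0.35, 0),
                      noise = list(photon_budget = 1e4, drift_nm = 1,
                                   read_sigma = 0.3), seed = 9)
  h2 <- form_hologram(sc, band600, c(0.35, 0),
                      noise = list(photon_budget = 1e4, drift_nm = 1,
                                   read_sigma = 0.3), seed = 9)
  expect_identical(h1$intensity, h2$intensity)

  # shot noise: variance tracks the mean in a uniform (fringe-free) scene
  sc0 <- mirror_scene(256, 0.5, 0)
  sc0$amp_r <- 0   # no fringes, flat intensity
  hp <- form_hologram(sc0, mono600, c(0.35, 0),
                      noise = list(photon_budget = 1e4), seed = 2)
  expect_equal(stats::var(as.vector(hp$intensity)) / mean(hp$intensity), 1,
               tolerance = 0.05)

  expect_error(form_hologram(sc, mono600, c(1.1, 0)), "Nyquist")
  expect_error(form_hologram(sc, mono600, c(0.35, 0),
                             noise = list(photon_budget = -5)), "budget")
})
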