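geom <- acquisition_geometry("mirror")

test_that("demodulation restores flat and piston scenes to sub-milliradian level", {
  h0 <- form_hologram(mirror_scene(256, 0.5, 0), mono600, geom$carrier)
  pm0 <- reconstruct_phase(h0, bandwidth = geom$bandwidth)
  inner <- pm0$phase[17:240, 17:240]
  expect_lt(stats::sd(inner), 1e-3)

  h1 <- form_hologram(mirror_scene(256, 0.5, 150), mono600, geom$carrier)
  pm1 <- reconstruct_phase(h1, bandwidth = geom$bandwidth)
  expect_equal(abs(piston_phase(pm1)), pi, tolerance = 1e-3)
})

test_that("wrapped lens retardance is recovered pixelwise away from the border", {
  n <- 512; pitch <- 500 / n
  sc <- gp_lens_scene(n, pitch, 100)
  h <- form_hologram(sc, band600, c(0.35, 0))
  pm <- reconstruct_phase(h, bandwidth = 0.15, apodize = FALSE)
  truth <- wrap_pv(2 * sc$truth$single_pass_phase)
  err <- abs(wrap_pv(pm$phase - truth))[65:(n - 64), 65:(n - 64)]
  expect_lt(max(err), 1e-2)
})

test_that("wrapped_phase takes the principal value and flags dead pixels", {
  f <- structure(list(field = matrix(exp(0.3i), 4, 4), pitch = 1,
                      meta = list()), class = "complex_field")
  expect_equal(wrapped_phase(f)$phase, matrix(0.3, 4, 4))

  f$field <- matrix(exp(1i * (pi + 0.1)), 4, 4)
  expect_equal(wrapped_phase(f)$phase, matrix(-pi + 0.1, 4, 4))

  f$field[2, 2] <- 0
  pm <- wrapped_phase(f)
  expect_equal(pm$phase[2, 2], 0)
  expect_true(pm$meta$low_quality[2, 2])
  expect_true(pm$wrapped)
})

test_that("background compensation subtracts references and low-order polynomials", {
  set.seed(1)
  p <- phase_map(matrix(stats::runif(64 * 64, -3, 3), 64, 64), 0.5)
  z <- subtract_background(p, reference = p)
  expect_equal(max(abs(z$phase)), 0)

  co_x <- outer(rep(1, 64), seq_len(64)); co_y <- outer(seq_len(64), rep(1, 64))
  tilt <- phase_map(0.01 * co_x - 0.02 * co_y + 0.5, 0.5, wrapped = FALSE)
  res <- subtract_background(tilt, poly_order = 1)
  expect_lt(stats::sd(res$phase), 1e-6)

  # SLM scene minus non-addressed background leaves the programmed block
  m <- matrix(0, 5, 5); m[2:4, 2:4] <- 1.2
  sa <- slm_scene(128, 0.5, pixel_size = 8, phase_matrix = m)
  sb <- slm_scene(128, 0.5, pixel_size = 8, phase_matrix = matrix(0, 5, 5))
  pa <- phase_map(sa$phi_s(600), 0.5)
  pb <- phase_map(sb$phi_s(600), 0.5)
  d <- subtract_background(pa, reference = pb)
  expect_equal(sort(unique(as.vector(d$phase))), c(0, 1.2), tolerance = 1e-12)

  expect_error(subtract_background(p, reference = phase_map(matrix(0, 2, 2), 0.5)),
               "mismatch")
})

test_that("least-squares unwrapping is exact on smooth wrapped inputs", {
  # smooth map with no wraps: unchanged up to a constant
  sm <- phase_map(matrix(0.3 * sin(seq(0, pi, length.out = 64)), 64, 64), 1)
  u <- unwrap(sm)
  expect_lt(diff(range(u$phase - sm$phase)), 1e-9)
  expect_equal(u$meta$n_residues, 0L)

  # lens quadratic spanning > 6 wraps over the field: exact after offset
  n <- 256
  sc <- gp_lens_scene(n, 500 / n, 30)   # short focus multiplies the wrap count
  ret <- 2 * sc$truth$single_pass_phase
  expect_gt(diff(range(ret)) / (2 * pi), 6)
  u2 <- unwrap(phase_map(wrap_pv(ret), 500 / n))
  d <- u2$phase - ret
  expect_lt(max(abs(d - mean(d))), 1e-2)

  # 1-D ramp of 10*pi against the cumulative-difference oracle
  x <- seq(0, 10 * pi, length.out = 300)
  expect_equal(unwrap_1d(wrap_pv(x)), x, tolerance = 1e-12)
  ramp2d <- phase_map(matrix(x[1:256], 16, 16)[, 1:16], 1)
  expect_false(unwrap(ramp2d)$wrapped)
})

test_that("demodulation is linear and insensitive to global intensity scale", {
  sc <- mirror_scene(128, 0.5, 120)
  h <- form_hologram(sc, mono600, geom$carrier)
  f1 <- demodulate(h, bandwidth = geom$bandwidth)

  h2 <- h; h2$intensity <- 2.5 * h$intensity
  f2 <- demodulate(h2, bandwidth = geom$bandwidth)
  expect_equal(f2$field, 2.5 * f1$field, tolerance = 1e-12)
  expect_equal(wrapped_phase(f2)$phase, wrapped_phase(f1)$phase,
               tolerance = 1e-9)

  ha <- h; hb <- h
  hb$intensity <- matrix(stats::runif(128 * 128), 128, 128)
  hsum <- h; hsum$intensity <- ha$intensity + hb$intensity
  fs <- demodulate(hsum, bandwidth = geom$bandwidth)
  fa <- demodulate(ha, bandwidth = geom$bandwidth)
  fb <- demodulate(hb, bandwidth = geom$bandwidth)
  expect_equal(fs$field, fa$field + fb$field, tolerance = 1e-10)

  expect_error(demodulate(h, bandwidth = 0.3), "overlap")
})

test_that("phase maps round-trip through float TIFF with sidecar", {
  set.seed(4)
  p <- phase_map(matrix(stats::rnorm(32 * 32, 0, 2), 32, 32), 0.25,
                 wrapped = FALSE, meta = list(note = "test"))
  path <- tempfile(fileext = ".tiff")
  write_phase_map(p, path)
  q <- read_phase_map(path)
  expect_equal(q$phase, p$phase, tolerance = 1e-6)   # float32 storage
  expect_identical(q$wrapped, FALSE)
  expect_equal(q$pitch, 0.25)
})
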