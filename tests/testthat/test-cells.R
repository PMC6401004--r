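dm_of <- function(m, pitch = 0.5) {
  structure(list(density = m, pitch = pitch), class = "drymass_map")
}

test_that("measure_cells arithmetic matches the definitions", {
  lab <- matrix(0L, 20, 20)
  lab[3:12, 3:12] <- 1L           # 100 pixels
  li <- structure(list(labels = lab, pitch = 0.5, meta = list()),
                  class = "label_image")
  tb <- measure_cells(li, dm_of(matrix(2, 20, 20)))
  expect_equal(tb$area_um2, 100 * 0.25)
  expect_equal(tb$mean_density_pg_um2, 2)
  expect_equal(tb$total_mass_pg, 200 * 0.25)

  # background-only input gives an empty table
  li0 <- structure(list(labels = matrix(0L, 8, 8), pitch = 0.5, meta = list()),
                   class = "label_image")
  expect_equal(nrow(measure_cells(li0, dm_of(matrix(1, 8, 8)))), 0L)

  expect_error(measure_cells(li, dm_of(matrix(1, 4, 4))), "mismatch")
})

test_that("per-cell masses are subadditive against the image total", {
  sc <- cell_phantom(256, 0.5, n_cells = 3, seed = 4)
  dm <- dm_of(sc$truth$density)
  lab <- segment_cells(dm)
  tb <- measure_cells(lab, dm)
  expect_lte(sum(tb$total_mass_pg), sum(dm$density) * 0.25 + 1e-9)
})

test_that("watershed segmentation finds well-separated phantom cells", {
  sc <- cell_phantom(512, 0.25, n_cells = 5, seed = 7, radius_range = c(6, 9))
  dm <- dm_of(sc$truth$density, 0.25)
  lab <- segment_cells(dm)
  expect_equal(max(lab$labels), 5L)

  # every ground-truth centroid falls inside exactly one label
  cen <- sc$truth$centers
  ids <- vapply(seq_len(nrow(cen)), function(i) {
    cx <- round(cen[i, 1] / 0.25 + (512 - 1) / 2) + 1L
    cy <- round(cen[i, 2] / 0.25 + (512 - 1) / 2) + 1L
    lab$labels[cy, cx]
  }, 0L)
  expect_setequal(ids, 1:5)

  # all-zero map: zero labels with a warning status
  expect_warning(l0 <- segment_cells(dm_of(matrix(0, 32, 32))), "empty")
  expect_equal(max(l0$labels), 0L)
})

test_that("shallow-contrast blob pairs under-segment when h exceeds the saddle", {
  co <- (1:128 - 64.5) * 0.5
  r1s <- outer(co^2, (co + 4.5)^2, `+`)
  r2s <- outer(co^2, (co - 4.5)^2, `+`)
  two <- exp(-r1s / 18) + exp(-r2s / 18)  # peak ~1.01, saddle ~0.65
  dm <- dm_of(two)
  merged <- segment_cells(dm, smoothing_sigma = 0.5,
                          background_threshold = 0.2, h_depth = 0.5)
  expect_equal(max(merged$labels), 1L)         # documented under-segmentation
  split <- segment_cells(dm, smoothing_sigma = 0.5,
                         background_threshold = 0.2, h_depth = 0.02)
  expect_equal(max(split$labels), 2L)
})

test_that("segmentation is invariant to joint rescaling of density and thresholds", {
  sc <- cell_phantom(256, 0.5, n_cells = 2, seed = 9)
  dm <- dm_of(sc$truth$density)
  l1 <- segment_cells(dm, background_threshold = 0.3, h_depth = 0.1)
  dm10 <- dm_of(10 * sc$truth$density)
  l2 <- segment_cells(dm10, background_threshold = 3, h_depth = 1)
  expect_identical(l1$labels, l2$labels)
})

test_that("tracking links static phantoms and terminates vanished cells", {
  sc <- cell_phantom(256, 0.5, n_cells = 3, seed = 12)
  dm <- dm_of(sc$truth$density)
  lab <- segment_cells(dm)
  tb <- measure_cells(lab, dm)
  labs <- list(); tbs <- list()
  for (f in 1:5) {
    labs[[f]] <- lab
    t_f <- tb; t_f$frame <- f
    tbs[[f]] <- t_f
  }
  tr <- track_cells(labs, tbs)
  lens <- table(tr$trajectory)
  expect_true(all(lens == 5))
  for (id in unique(tr$trajectory))
    expect_equal(stats::sd(tr$area_um2[tr$trajectory == id]), 0)

  # a cell leaving the field ends its trajectory; labels are not reused
  lab2 <- lab
  lab2$labels[lab$labels == 3L] <- 0L
  tb2 <- measure_cells(lab2, dm, frame = 2L)
  tr2 <- track_cells(list(lab, lab2), list(tb, tb2))
  expect_equal(sum(tr2$frame == 2), 2L)
  expect_equal(length(unique(tr2$trajectory)), 3L)
})

test_that("end-to-end phantom imaging recovers per-cell dry mass within 5%", {
  res <- run_cells(n_frames = 1, n_cells = 4, seed = 2)
  tb <- res$tables[[1]]
  truth <- res$truth[[1]]
  expect_equal(nrow(tb), nrow(truth))
  m_meas <- sort(tb$total_mass_pg)
  m_true <- sort(truth$total_mass_pg)
  expect_true(all(abs(m_meas / m_true - 1) < 0.05))
})

test_that("growth trends in area and mean density are recovered from time lapse", {
  res <- run_cells(n_frames = 4, n_cells = 4, seed = 2,
                   area_growth = 0.02, mass_growth = 0)
  tr <- res$trajectories
  ids <- unique(tr$trajectory)
  slopes <- vapply(ids, function(id) {
    a <- tr$area_um2[tr$trajectory == id]
    mean(diff(a) / a[-length(a)])
  }, 0)
  expect_equal(mean(slopes), 0.02, tolerance = 0.1)
  # area up, mean density down (mass fixed while area grows)
  dens_trend <- vapply(ids, function(id) {
    mean(diff(tr$mean_density_pg_um2[tr$trajectory == id]))
  }, 0)
  expect_true(all(dens_trend < 0))
})
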