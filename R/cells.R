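#' Watershed segmentation of a dry-mass density map
#'
#' Pipeline: Gaussian smoothing, foreground mask by threshold (Otsu on the
#' smoothed map unless overridden), marker-controlled watershed on the
#' smoothed density with h-maxima depth `h_depth`, and finally label
#' propagation into a slightly dilated mask so the smooth rim of each cell
#' (pushed below threshold by diffraction and smoothing) is attributed to
#' its cell rather than to background -- without this expansion a
#' threshold-bounded label systematically misses the rim mass.
#'
#' The watershed, blur, Otsu threshold and propagation primitives are the
#' EBImage implementations.
#'
#' @param density a `drymass_map`.
#' @param smoothing_sigma Gaussian smoothing width, um.
#' @param background_threshold foreground threshold, pg/um^2; NULL for Otsu
#'   on the smoothed map.
#' @param h_depth marker depth for the watershed, pg/um^2; NULL for 10% of
#'   the smoothed map's dynamic range.
#' @param mask_dilation expansion of the foreground mask, um (default 0:
#'   labels end at the outline contour; use [measure_cells()]'s `expand`
#'   to capture rim mass).
#' @param outline `"halfmax"` (default) trims every label to the contour
#'   at half of its own plateau density (90th percentile), which pins the
#'   outline to the morphological cell boundary independent of rim width
#'   and of the global threshold, so label areas track cell growth;
#'   `"threshold"` keeps the raw threshold/watershed footprint.
#' @return A `label_image`: list with `labels` (integer matrix, 0 =
#'   background, consecutive labels), `pitch`, `meta` (threshold used,
#'   warning status).
#' @export
segment_cells <- function(density, smoothing_sigma = 1,
                          background_threshold = NULL, h_depth = NULL,
                          mask_dilation = 0,
                          outline = c("halfmax", "threshold")) {
  outline <- match.arg(outline)
  stopifnot(inherits(density, "drymass_map"))
  d <- density$density
  pitch <- density$pitch
  sm <- if (smoothing_sigma > 0)
    .gaussian_blur(d, smoothing_sigma / pitch) else d
  rng <- range(sm)
  if (is.null(background_threshold)) {
    norm <- (sm - rng[1L]) / max(rng[2L] - rng[1L], .Machine$double.eps)
    background_threshold <- rng[1L] +
      EBImage::otsu(EBImage::Image(norm)) * (rng[2L] - rng[1L])
  }
  if (is.null(h_depth)) h_depth <- 0.1 * (rng[2L] - rng[1L])
  fg <- sm > background_threshold
  if (!any(fg)) {
    warning("segment_cells: empty foreground; returning all-background")
    return(structure(list(labels = matrix(0L, nrow(d), ncol(d)), pitch = pitch,
                          meta = list(threshold = background_threshold,
                                      status = "empty")),
                     class = "label_image"))
  }
  relief <- sm
  relief[!fg] <- 0
  ws <- EBImage::watershed(EBImage::Image(relief), tolerance = h_depth, ext = 1)
  lab <- EBImage::imageData(ws)
  if (mask_dilation > 0 && max(lab) > 0) {
    r <- max(1L, round(mask_dilation / pitch))
    kern <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    grown <- EBImage::dilate(EBImage::Image(fg * 1), kern) > 0
    lab <- EBImage::imageData(
      EBImage::propagate(EBImage::Image(sm), EBImage::Image(lab),
                         mask = EBImage::Image(grown)))
  }
  if (outline == "halfmax" && max(lab) > 0) {
    for (i in unique(as.integer(lab[lab > 0]))) {
      inlab <- lab == i
      plateau <- stats::quantile(sm[inlab], 0.9, names = FALSE)
      lab[inlab & sm < 0.5 * plateau] <- 0L
    }
  }
  # consecutive positive integers
  u <- sort(unique(as.integer(lab[lab > 0])))
  out <- matrix(0L, nrow(d), ncol(d))
  for (i in seq_along(u)) out[lab == u[i]] <- i
  structure(list(labels = out, pitch = pitch,
                 meta = list(threshold = background_threshold,
                             h_depth = h_depth, outline = outline,
                             status = "ok")),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image>  %d x %d px, pitch %.4g um, %d label(s)\n",
              nrow(x$labels), ncol(x$labels), x$pitch, max(x$labels)))
  invisible(x)
}

#' Per-cell morphometrics
#'
#' For each label: area (pixel count x pitch^2, um^2), mean dry-mass
#' density over the label (pg/um^2), total dry mass (sum x pitch^2, pg).
#'
#' With `expand > 0` the mass integration support of every label is grown
#' by that many micrometers (label competition resolved by EBImage
#' propagation), capturing the smooth rim that thresholding leaves outside
#' the label; the area is still the core label's, and the mean density is
#' then total mass over core area.
#'
#' @param labels a `label_image`.
#' @param density a `drymass_map` on the same grid.
#' @param frame frame index recorded in the table.
#' @param expand rim-capture expansion of the mass support, um.
#' @return A `cell_table` (empty when there are no labels).
#' @export
measure_cells <- function(labels, density, frame = 1L, expand = 0) {
  stopifnot(inherits(labels, "label_image"), inherits(density, "drymass_map"))
  if (!all(dim(labels$labels) == dim(density$density)))
    stop("measure_cells: grid mismatch between labels and density")
  l <- labels$labels
  if (max(l) == 0L) {
    return(cell_table(data.frame(frame = integer(), label = integer(),
                                 area_um2 = numeric(),
                                 mean_density_pg_um2 = numeric(),
                                 total_mass_pg = numeric())))
  }
  sel <- l > 0L
  f <- factor(l[sel], levels = seq_len(max(l)))
  npx <- as.integer(table(f))
  area <- npx * labels$pitch^2
  lm <- l
  if (expand > 0) {
    r <- max(1L, round(expand / labels$pitch))
    kern <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
    grown <- EBImage::dilate(EBImage::Image((l > 0L) * 1), kern) > 0
    lm <- EBImage::imageData(
      EBImage::propagate(EBImage::Image(density$density), EBImage::Image(l),
                         mask = EBImage::Image(grown)))
  }
  fm <- factor(lm[lm > 0L], levels = seq_len(max(l)))
  tot <- as.numeric(tapply(density$density[lm > 0L], fm, sum, default = 0))
  tot[is.na(tot)] <- 0
  mass <- tot * labels$pitch^2
  mean_density <- if (expand > 0) mass / area else {
    core_tot <- as.numeric(tapply(density$density[sel], f, sum, default = 0))
    core_tot / npx
  }
  cell_table(data.frame(frame = as.integer(frame),
                        label = seq_len(max(l)),
                        area_um2 = area,
                        mean_density_pg_um2 = mean_density,
                        total_mass_pg = mass))
}

#' Frame-to-frame cell tracking by label overlap
#'
#' Greedy maximum-overlap matching of labels between consecutive frames:
#' each pair of labels sharing at least `min_overlap` of the smaller
#' label's area (and being the best mutual match) continues a trajectory;
#' unmatched labels start or end trajectories and identifiers are never
#' reused.
#'
#' @param labels_list list of `label_image`s (>= 2 frames).
#' @param tables_list list of matching `cell_table`s ([measure_cells()]).
#' @param min_overlap minimum overlap fraction.
#' @return data.frame with columns `frame`, `label`, `trajectory`,
#'   `area_um2`, `mean_density_pg_um2`, `total_mass_pg`.
#' @export
track_cells <- function(labels_list, tables_list, min_overlap = 0.3) {
  stopifnot(length(labels_list) >= 2L,
            length(labels_list) == length(tables_list))
  n_frames <- length(labels_list)
  traj_of <- vector("list", n_frames)   # label -> trajectory id per frame
  next_id <- 0L
  t1 <- tables_list[[1L]]
  traj_of[[1L]] <- seq_len(max(0L, max(labels_list[[1L]]$labels)))
  next_id <- length(traj_of[[1L]])
  for (f in 2L:n_frames) {
    la <- labels_list[[f - 1L]]$labels
    lb <- labels_list[[f]]$labels
    na <- max(la); nb <- max(lb)
    traj_of[[f]] <- rep(NA_integer_, nb)
    if (na > 0L && nb > 0L) {
      both <- la > 0L & lb > 0L
      ov <- table(factor(la[both], levels = seq_len(na)),
                  factor(lb[both], levels = seq_len(nb)))
      size_a <- tabulate(la[la > 0L], na)
      size_b <- tabulate(lb[lb > 0L], nb)
      cand <- which(ov > 0, arr.ind = TRUE)
      if (nrow(cand) > 0L) {
        frac <- ov[cand] / pmin(size_a[cand[, 1L]], size_b[cand[, 2L]])
        ord <- order(ov[cand], decreasing = TRUE)
        used_a <- logical(na); used_b <- logical(nb)
        for (k in ord) {
          ia <- cand[k, 1L]; ib <- cand[k, 2L]
          if (!used_a[ia] && !used_b[ib] && frac[k] >= min_overlap) {
            traj_of[[f]][ib] <- traj_of[[f - 1L]][ia]
            used_a[ia] <- TRUE; used_b[ib] <- TRUE
          }
        }
      }
    }
    for (ib in which(is.na(traj_of[[f]]))) {
      next_id <- next_id + 1L
      traj_of[[f]][ib] <- next_id
    }
  }
  rows <- lapply(seq_len(n_frames), function(f) {
    tab <- tables_list[[f]]
    if (nrow(tab) == 0L) return(NULL)
    cbind(tab[, c("frame", "label")],
          trajectory = traj_of[[f]][tab$label],
          tab[, c("area_um2", "mean_density_pg_um2", "total_mass_pg")])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a label image as 16-bit TIFF
#' @param labels a `label_image`.
#' @param path output path.
#' @export
write_label_image <- function(labels, path) {
  tiff::writeTIFF(labels$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' Write a cell table or trajectory table as CSV
#' @param tab a data.frame (`cell_table` or [track_cells()] output).
#' @param path output path.
#' @export
write_cell_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
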