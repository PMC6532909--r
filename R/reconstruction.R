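#' Confocal image stack of a pillar device
#'
#' Container for a 3D fluorescence stack: a list of 2D intensity slices
#' (matrices in `[0, 1]`, slice 1 = pillar base at `z = 0`), the lateral
#' pixel size and the axial step. Slice `i` sits at height
#' `z = (i - 1) * z_step`, so a 75-slice stack at 4 um steps covers
#' 0-296 um of a 300 um pillar.
#'
#' @param slices list of numeric matrices, all of equal dimension.
#' @param pixel_size_um lateral pixel size (um/pixel).
#' @param z_step_um axial slice spacing (um).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(slices, pixel_size_um, z_step_um) {
  stopifnot(is.list(slices), length(slices) >= 2,
            all(vapply(slices, is.matrix, logical(1))))
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices must share one image size", call. = FALSE)
  if (pixel_size_um <= 0 || z_step_um <= 0)
    stop("pixel size and z step must be positive", call. = FALSE)
  structure(list(slices = slices, pixel_size = pixel_size_um,
                 z_step = z_step_um, n_z = length(slices)),
            class = "image_stack")
}

#' Read a multi-page TIFF stack and its JSON sidecar
#'
#' The sidecar carries the acquisition metadata the pixels cannot:
#' `pixel_size_um`, `z_step_um`, `n_pillars` and `expected_radius_um`.
#'
#' @param tiff_path multi-page grayscale TIFF (8- or 16-bit).
#' @param sidecar_path JSON sidecar; defaults to the TIFF path with a
#'   `.json` extension.
#' @return An `image_stack` with the sidecar fields attached as attributes
#'   `n_pillars` and `expected_radius_um`.
#' @export
read_image_stack <- function(tiff_path, sidecar_path = NULL) {
  if (is.null(sidecar_path)) sidecar_path <- sub("\\.tiff?$", ".json", tiff_path)
  pages <- tiff::readTIFF(tiff_path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (key in c("pixel_size_um", "z_step_um"))
    if (is.null(meta[[key]])) stop("sidecar is missing ", key, call. = FALSE)
  st <- image_stack(pages, meta$pixel_size_um, meta$z_step_um)
  attr(st, "n_pillars") <- meta$n_pillars
  attr(st, "expected_radius_um") <- meta$expected_radius_um
  st
}

# Otsu threshold of a numeric matrix, guarded for flat input.
otsu_threshold <- function(img) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(img, range = rng)
}

# Measure one labelled component: intensity-weighted sub-pixel centroid
# (pixels), equivalent-area radius (pixels) and disk-template energy.
measure_component <- function(img, label_mask) {
  idx <- which(label_mask, arr.ind = TRUE)
  w <- img[label_mask]
  cen <- weighted_centroid(idx[, 1], idx[, 2], w)
  r_px <- sqrt(nrow(idx) / pi)
  half <- ceiling(r_px) + 3
  r0 <- max(1, floor(cen["y"] + 0.5) - half); r1 <- min(nrow(img), floor(cen["y"] + 0.5) + half)
  c0 <- max(1, floor(cen["x"] + 0.5) - half); c1 <- min(ncol(img), floor(cen["x"] + 0.5) + half)
  patch <- img[r0:r1, c0:c1, drop = FALSE]
  energy <- disk_template_energy(patch, cen["x"] - (c0 - 1), cen["y"] - (r0 - 1), r_px)
  list(cx_px = unname(cen["x"]), cy_px = unname(cen["y"]),
       r_px = r_px, area_px = nrow(idx), energy = energy)
}

#' Segment the pillar bases on the first slice
#'
#' Step one of the 3D reconstruction: the first slice of the stack shows
#' the undeflected pillar bases as bright disks on a dark background. The
#' slice is normalized, thresholded (Otsu), and connected components above
#' a minimal area (a quarter of the expected disk area) are measured:
#' intensity-weighted sub-pixel centroid, equivalent-area radius and a
#' confidence energy defined as the normalized cross-correlation of the
#' local patch with an ideal disk template. The `n_expected` detections of
#' highest energy are kept, ordered by angle around their common centre so
#' pillar identities are reproducible.
#'
#' @param stack an [image_stack()].
#' @param expected_radius_um nominal pillar radius (um).
#' @param n_expected number of pillars in the device.
#' @return Data frame with one row per pillar: `pillar_id`, `x_um`, `y_um`,
#'   `radius_um`, `energy`.
#' @export
segment_base_slice <- function(stack, expected_radius_um, n_expected) {
  stopifnot(inherits(stack, "image_stack"), n_expected >= 1)
  img <- stack$slices[[1]]
  if (max(img) > min(img)) img <- (img - min(img)) / (max(img) - min(img))
  thr <- otsu_threshold(img)
  mask <- img > thr
  lab <- EBImage::bwlabel(mask)
  n_lab <- max(lab)
  r_px <- expected_radius_um / stack$pixel_size
  min_area <- 0.25 * pi * r_px^2
  comps <- list()
  for (k in seq_len(n_lab)) {
    sel <- lab == k
    if (sum(sel) < min_area) next
    comps[[length(comps) + 1L]] <- measure_component(img, sel)
  }
  if (length(comps) < n_expected)
    stop(sprintf("expected %d pillar bases but found %d disk-like components",
                 n_expected, length(comps)), call. = FALSE)
  df <- do.call(rbind, lapply(comps, as.data.frame))
  df <- df[order(-df$energy), ][seq_len(n_expected), ]
  ang <- atan2(df$cy_px - mean(df$cy_px), df$cx_px - mean(df$cx_px))
  df <- df[order(ang), ]
  data.frame(pillar_id = seq_len(n_expected),
             x_um = px_x(df$cx_px + 0.5, stack$pixel_size),
             y_um = px_y(df$cy_px + 0.5, stack$pixel_size),
             radius_um = df$r_px * stack$pixel_size,
             energy = df$energy)
}

#' Track one pillar from the previous slice into the current slice
#'
#' Step two of the reconstruction: the detection on slice `i - 1` defines a
#' search region on slice `i` — a window of half-width
#' `search_radius + radius` around the previous centre. The window is
#' thresholded (Otsu, with an absolute intensity floor guarding against
#' empty regions at strong depth attenuation), and the connected component
#' whose centroid is nearest the previous centre, within the search radius,
#' is re-measured. If nothing acceptable is found the detection is marked
#' invalid and tracking continues from the last valid slice.
#'
#' @param prev list or one-row data frame with `x_um`, `y_um`, `radius_um`
#'   of the previous detection.
#' @param slice_img intensity matrix of the current slice (same
#'   normalization as the rest of the stack).
#' @param pixel_size_um lateral pixel size (um).
#' @param search_radius_um maximal plausible centre shift between adjacent
#'   slices (um); default 7 um.
#' @param intensity_floor absolute floor on the window maximum below which
#'   the slice is declared invalid; on the stack's normalized scale.
#' @return List: `x_um`, `y_um`, `radius_um`, `energy`, `valid`.
#' @export
propagate_slice <- function(prev, slice_img, pixel_size_um,
                            search_radius_um = 7, intensity_floor = 0.05) {
  cx <- prev$x_um / pixel_size_um   # sub-pixel, in pixel units
  cy <- prev$y_um / pixel_size_um
  half <- ceiling((search_radius_um + prev$radius_um) / pixel_size_um) + 3L
  r0 <- max(1L, floor(cy) - half); r1 <- min(nrow(slice_img), floor(cy) + half)
  c0 <- max(1L, floor(cx) - half); c1 <- min(ncol(slice_img), floor(cx) + half)
  invalid <- list(x_um = prev$x_um, y_um = prev$y_um, radius_um = prev$radius_um,
                  energy = 0, valid = FALSE)
  if (r1 <= r0 || c1 <= c0) return(invalid)
  win <- slice_img[r0:r1, c0:c1, drop = FALSE]
  if (max(win) < intensity_floor) return(invalid)
  thr <- otsu_threshold(win)
  lab <- EBImage::bwlabel(win > thr)
  n_lab <- max(lab)
  if (n_lab == 0) return(invalid)
  best <- NULL
  best_dist <- Inf
  for (k in seq_len(n_lab)) {
    sel <- lab == k
    if (sum(sel) < 4) next
    m <- measure_component(win, sel)
    dx <- (m$cx_px + c0 - 1) - cx
    dy <- (m$cy_px + r0 - 1) - cy
    dist_um <- sqrt(dx^2 + dy^2) * pixel_size_um
    if (dist_um <= search_radius_um && dist_um < best_dist) {
      best <- m
      best_dist <- dist_um
    }
  }
  if (is.null(best)) return(invalid)
  list(x_um = px_x(best$cx_px + c0 - 1 + 0.5, pixel_size_um),
       y_um = px_y(best$cy_px + r0 - 1 + 0.5, pixel_size_um),
       radius_um = best$r_px * pixel_size_um,
       energy = best$energy, valid = TRUE)
}

#' Smooth a pillar skeleton along z
#'
#' Step three of the reconstruction: the per-slice centres form a noisy
#' skeleton that is smoothed with an energy-weighted cubic smoothing spline
#' per coordinate versus height. Slices with invalid detections (or zero
#' energy) are excluded from the fit and receive spline-interpolated
#' values, flagged as imputed. `df = 0` disables the roughness penalty and
#' interpolates the valid centres exactly with a cubic spline.
#'
#' @param z slice heights (um).
#' @param x,y per-slice centre coordinates (um).
#' @param energy per-slice confidence weights in `[0, 1]`; `NULL` for
#'   uniform weights.
#' @param valid logical mask of trustworthy slices; `NULL` for all valid.
#' @param df equivalent degrees of freedom of the smoothing spline;
#'   default 8 balances noise suppression against the curvature of a bent
#'   pillar, and is capped at the number of fitted points minus one.
#' @return List with smoothed `x`, `y` and a logical `imputed` mask.
#' @export
smooth_skeleton <- function(z, x, y, energy = NULL, valid = NULL, df = 8) {
  n <- length(z)
  stopifnot(length(x) == n, length(y) == n)
  if (is.null(energy)) energy <- rep(1, n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  use <- valid & energy > 0 & is.finite(x) & is.finite(y)
  if (sum(use) < 4)
    stop("fewer than 4 valid slices; skeleton unusable", call. = FALSE)
  fit_coord <- function(v) {
    if (df == 0)
      return(stats::splinefun(z[use], v[use], method = "fmm")(z))
    eff_df <- min(df, sum(use) - 1)
    sp <- stats::smooth.spline(z[use], v[use], w = energy[use], df = eff_df)
    stats::predict(sp, z)$y
  }
  list(x = fit_coord(x), y = fit_coord(y), imputed = !use)
}

# Scalar deflection of one pillar: signed projection of the per-slice
# displacement (relative to the base-slice centre) onto the pillar's mean
# displacement direction, so a radially pushed pillar gets a positive,
# monotone profile while sign information survives for non-radial cases.
scalar_deflection <- function(dx, dy) {
  dir <- c(mean(dx), mean(dy))
  nrm <- sqrt(sum(dir^2))
  if (nrm < 1e-9) {
    k <- which.max(dx^2 + dy^2)
    dir <- c(dx[k], dy[k])
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-12) return(list(d = rep(0, length(dx)), direction = c(1, 0)))
  }
  dir <- dir / nrm
  list(d = dx * dir[1] + dy * dir[2], direction = dir)
}

#' Reconstruct per-pillar deflection profiles from a z-stack
#'
#' Runs the full three-step reconstruction: base segmentation on the first
#' slice, slice-by-slice upward propagation of every pillar, and skeleton
#' smoothing. Pixel coordinates are converted to um and each pillar's
#' scalar deflection `d_i` is computed as the signed projection of the
#' slice-`i` centre displacement (relative to the base-slice centre) onto
#' the pillar's mean displacement direction; `d` is zero at the base by
#' construction. Slices where tracking failed carry interpolated centres
#' flagged `valid = FALSE` and are excluded from downstream force fits.
#'
#' @param stack an [image_stack()].
#' @param n_pillars number of pillars; defaults to the stack attribute from
#'   the sidecar.
#' @param expected_radius_um nominal pillar radius (um); sidecar default.
#' @param search_radius_um per-slice search radius (um), default 7.
#' @param smooth_df smoothing-spline degrees of freedom, see
#'   [smooth_skeleton()].
#' @param intensity_floor see [propagate_slice()].
#' @return An object of class `pillar_profiles`: a list of `pillar_profile`
#'   data frames (`slice`, `z_um`, `x_um`, `y_um`, `d_um`, `radius_um`,
#'   `energy`, `valid`), each with attributes `pillar_id`, `base_um` and
#'   `direction`.
#' @export
reconstruct_stack <- function(stack, n_pillars = attr(stack, "n_pillars"),
                              expected_radius_um = attr(stack, "expected_radius_um"),
                              search_radius_um = 7, smooth_df = 8,
                              intensity_floor = 0.05) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.null(n_pillars) || is.null(expected_radius_um))
    stop("n_pillars and expected_radius_um must be given (or present in the sidecar)",
         call. = FALSE)
  gmax <- max(vapply(stack$slices, max, numeric(1)))
  slices <- if (gmax > 0) lapply(stack$slices, function(s) s / gmax) else stack$slices
  norm_stack <- image_stack(slices, stack$pixel_size, stack$z_step)

  base <- segment_base_slice(norm_stack, expected_radius_um, n_pillars)
  z <- (seq_len(stack$n_z) - 1) * stack$z_step

  profiles <- lapply(seq_len(n_pillars), function(p) {
    x <- y <- r <- en <- numeric(stack$n_z)
    ok <- logical(stack$n_z)
    x[1] <- base$x_um[p]; y[1] <- base$y_um[p]
    r[1] <- base$radius_um[p]; en[1] <- base$energy[p]; ok[1] <- TRUE
    last <- list(x_um = x[1], y_um = y[1], radius_um = r[1])
    for (i in 2:stack$n_z) {
      det <- propagate_slice(last, slices[[i]], stack$pixel_size,
                             search_radius_um, intensity_floor)
      x[i] <- det$x_um; y[i] <- det$y_um; r[i] <- det$radius_um
      en[i] <- det$energy; ok[i] <- det$valid
      if (det$valid) last <- det
    }
    if (sum(ok) < 4) {
      prof <- data.frame(slice = seq_len(stack$n_z), z_um = z, x_um = x,
                         y_um = y, d_um = NA_real_, radius_um = r,
                         energy = en, valid = FALSE)
      attr(prof, "pillar_id") <- p
      attr(prof, "usable") <- FALSE
      class(prof) <- c("pillar_profile", "data.frame")
      return(prof)
    }
    sk <- smooth_skeleton(z, x, y, energy = en, valid = ok, df = smooth_df)
    dx <- sk$x - sk$x[1]
    dy <- sk$y - sk$y[1]
    sc <- scalar_deflection(dx, dy)
    prof <- data.frame(slice = seq_len(stack$n_z), z_um = z,
                       x_um = sk$x, y_um = sk$y, d_um = sc$d,
                       radius_um = r, energy = en, valid = ok)
    attr(prof, "pillar_id") <- p
    attr(prof, "usable") <- TRUE
    attr(prof, "base_um") <- c(sk$x[1], sk$y[1])
    attr(prof, "direction") <- sc$direction
    class(prof) <- c("pillar_profile", "data.frame")
    prof
  })
  structure(profiles, class = "pillar_profiles")
}

#' Write reconstructed profiles to CSV
#'
#' One row per pillar and slice with the documented columns `pillar_id`,
#' `slice`, `z_um`, `x_um`, `y_um`, `d_um`, `radius_um`, `energy`, `valid`.
#'
#' @param profiles a `pillar_profiles` list from [reconstruct_stack()].
#' @param path output CSV path.
#' @export
write_profiles_csv <- function(profiles, path) {
  stopifnot(inherits(profiles, "pillar_profiles"))
  rows <- lapply(profiles, function(p)
    cbind(pillar_id = attr(p, "pillar_id"), as.data.frame(p)))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
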