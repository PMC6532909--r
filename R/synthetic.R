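#' Define a synthetic pillar-device scene
#'
#' Describes a ring-shaped microdevice of cylindrical pillars bent by
#' prescribed forces, plus the optical degradations of deep confocal
#' imaging, so that ground-truth stacks can be rendered for end-to-end
#' validation. The defaults mirror the experimental devices: 12 pillars of
#' 28 um diameter and 300 um height on a ring sized for a ~300 um
#' spheroid, imaged as 75 slices at 4 um steps; forces push radially
#' outward, as a growing spheroid does.
#'
#' Optical degradations are an idealized stand-in for the confocal point
#' spread: a Gaussian blur whose width grows linearly from base to top
#' (reproducing the apparent size difference between pillar bottom and
#' top), a linear intensity attenuation with depth, and additive Gaussian
#' (optionally Poisson) noise. The spheroid body itself is not rendered:
#' only the dye-stained pillar channel is analysed.
#'
#' @param n_pillars number of pillars on the ring.
#' @param ring_radius_um ring radius to the pillar base centres (um).
#' @param diameter_um,height_um pillar dimensions (um).
#' @param E_MPa,nu,rho material constants (see [beam_material()]).
#' @param loaded_span_um loaded span from the pillar top (um).
#' @param forces_nN applied force per pillar (nN); recycled to `n_pillars`.
#' @param directions optional `n_pillars x 2` matrix of unit load
#'   directions; default radially outward from the ring centre.
#' @param blur_sigma_base_um,blur_sigma_top_um Gaussian blur width at the
#'   base and top slices (um); interpolated linearly in between.
#' @param attenuation_top fraction of intensity lost at the top slice, in
#'   `[0, 1)`.
#' @param noise_sigma standard deviation of additive Gaussian noise on the
#'   unit intensity scale.
#' @param poisson_noise logical; add photon shot noise (Poisson with
#'   `poisson_scale` expected counts at unit intensity).
#' @param poisson_scale expected photon count at unit intensity.
#' @param pixel_size_um,z_step_um,image_size_px raster parameters.
#' @param seed RNG seed; a fixed seed makes the rendered stack
#'   byte-identical across runs.
#' @return An object of class `synthetic_scene`.
#' @examples
#' sc <- synthetic_scene(forces_nN = 230)
#' @export
synthetic_scene <- function(n_pillars = 12, ring_radius_um = 160,
                            diameter_um = 28, height_um = 300,
                            E_MPa = 2.6, nu = 0.499, rho = 927,
                            loaded_span_um = 175,
                            forces_nN = 230, directions = NULL,
                            blur_sigma_base_um = 1, blur_sigma_top_um = 3,
                            attenuation_top = 0.3,
                            noise_sigma = 0.02, poisson_noise = FALSE,
                            poisson_scale = 500,
                            pixel_size_um = 2, z_step_um = 4,
                            image_size_px = 256, seed = 1) {
  stopifnot(n_pillars >= 1, ring_radius_um > 0)
  if (attenuation_top < 0 || attenuation_top >= 1)
    stop("attenuation_top must lie in [0, 1)", call. = FALSE)
  forces_nN <- rep_len(forces_nN, n_pillars)
  if (any(forces_nN < 0)) stop("forces must be non-negative", call. = FALSE)
  ang <- 2 * pi * (seq_len(n_pillars) - 1) / n_pillars
  centre <- image_size_px * pixel_size_um / 2
  bases <- cbind(x = centre + ring_radius_um * cos(ang),
                 y = centre + ring_radius_um * sin(ang))
  if (is.null(directions)) directions <- cbind(cos(ang), sin(ang))
  directions <- directions / sqrt(rowSums(directions^2))
  # pillars must not overlap at the base
  if (n_pillars > 1) {
    gap <- 2 * ring_radius_um * sin(pi / n_pillars)
    if (gap <= diameter_um)
      stop("pillars overlap at the base; enlarge the ring or reduce n_pillars",
           call. = FALSE)
  }
  structure(list(
    n_pillars = n_pillars, ring_radius = ring_radius_um, bases = bases,
    geom = pillar_geometry(d = diameter_um * 1e-6, h = height_um * 1e-6),
    mat = beam_material(E = E_MPa * 1e6, nu = nu, rho = rho),
    loaded_span = loaded_span_um * 1e-6,
    forces_nN = forces_nN, directions = directions,
    blur_sigma_base = blur_sigma_base_um, blur_sigma_top = blur_sigma_top_um,
    attenuation_top = attenuation_top,
    noise_sigma = noise_sigma, poisson_noise = poisson_noise,
    poisson_scale = poisson_scale,
    pixel_size = pixel_size_um, z_step = z_step_um,
    image_size = image_size_px,
    n_z = as.integer(ceiling(height_um / z_step_um)),
    seed = seed), class = "synthetic_scene")
}

#' Ground-truth bent centrelines of a scene
#'
#' Evaluates the beam-model deflection of each pillar at every slice height
#' and displaces the pillar's vertical axis along its load direction. The
#' mechanics module is the single source of truth for the bending shape,
#' so reconstruction and inversion are validated against exactly the curve
#' family they are meant to recover.
#'
#' @param scene a [synthetic_scene()].
#' @return Data frame (class `ground_truth`) with one row per pillar and
#'   slice: `pillar_id`, `slice`, `z_um`, `x_um`, `y_um`, `defl_um`,
#'   `radius_um`, `F_nN`.
#' @export
bend_centerlines <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  z_um <- (seq_len(scene$n_z) - 1) * scene$z_step
  z_m <- pmin(z_um * 1e-6, scene$geom$h)
  rows <- lapply(seq_len(scene$n_pillars), function(p) {
    w_um <- deflection_profile(scene$geom, scene$mat,
                               load_spec(F = scene$forces_nN[p] * 1e-9,
                                         s = scene$loaded_span),
                               z_m) * 1e6
    data.frame(pillar_id = p, slice = seq_len(scene$n_z), z_um = z_um,
               x_um = scene$bases[p, 1] + w_um * scene$directions[p, 1],
               y_um = scene$bases[p, 2] + w_um * scene$directions[p, 2],
               defl_um = w_um,
               radius_um = scene$geom$d * 1e6 / 2,
               F_nN = scene$forces_nN[p])
  })
  structure(do.call(rbind, rows), class = c("ground_truth", "data.frame"))
}

#' Render a synthetic confocal z-stack of the scene
#'
#' Draws, for each slice, anti-aliased bright disks at the ground-truth
#' centreline positions, blurs the slice with the z-interpolated Gaussian,
#' applies the depth attenuation, adds seeded noise and quantizes to the
#' 16-bit intensity grid (so in-memory voxels equal what a written TIFF
#' would read back). A pillar whose disk would leave the field of view
#' raises an error naming the pillar.
#'
#' @param scene a [synthetic_scene()].
#' @return List with `stack` (an [image_stack()] with sidecar attributes
#'   set) and `truth` (the [bend_centerlines()] table).
#' @export
render_stack <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  truth <- bend_centerlines(scene)
  n <- scene$image_size
  r_px <- (scene$geom$d * 1e6 / 2) / scene$pixel_size
  fov_um <- n * scene$pixel_size
  margin <- (scene$geom$d * 1e6 / 2) + 3 * scene$blur_sigma_top + 2 * scene$pixel_size
  out <- truth$x_um < margin | truth$x_um > fov_um - margin |
         truth$y_um < margin | truth$y_um > fov_um - margin
  if (any(out))
    stop("pillar(s) ", paste(unique(truth$pillar_id[out]), collapse = ", "),
         " leave the field of view; enlarge image_size_px", call. = FALSE)

  slices <- withr::with_seed(scene$seed, {
    lapply(seq_len(scene$n_z), function(i) {
      img <- matrix(0, n, n)
      tr <- truth[truth$slice == i, ]
      half <- ceiling(r_px) + 2L
      for (p in seq_len(nrow(tr))) {
        cx <- tr$x_um[p] / scene$pixel_size  # continuous pixel coords
        cy <- tr$y_um[p] / scene$pixel_size
        c0 <- floor(cx) - half; c1 <- floor(cx) + half
        r0 <- floor(cy) - half; r1 <- floor(cy) + half
        patch <- soft_disk_patch(r1 - r0 + 1, c1 - c0 + 1,
                                 cx - (c0 - 1), cy - (r0 - 1), r_px)
        img[r0:r1, c0:c1] <- pmax(img[r0:r1, c0:c1], patch)
      }
      frac <- (i - 1) / max(scene$n_z - 1, 1)
      sigma_px <- (scene$blur_sigma_base +
                     frac * (scene$blur_sigma_top - scene$blur_sigma_base)) /
        scene$pixel_size
      if (sigma_px > 0.05) img <- EBImage::gblur(img, sigma = sigma_px)
      img <- img * (1 - scene$attenuation_top * frac)
      if (scene$poisson_noise)
        img <- stats::rpois(length(img), img * scene$poisson_scale) /
          scene$poisson_scale
      if (scene$noise_sigma > 0)
        img <- img + stats::rnorm(length(img), sd = scene$noise_sigma)
      img <- matrix(pmin(pmax(img, 0), 1), n, n)
      round(img * 65535) / 65535
    })
  })
  stack <- image_stack(slices, scene$pixel_size, scene$z_step)
  attr(stack, "n_pillars") <- scene$n_pillars
  attr(stack, "expected_radius_um") <- scene$geom$d * 1e6 / 2
  list(stack = stack, truth = truth)
}

#' Write a rendered scene to disk
#'
#' Writes the 16-bit multi-page TIFF, the JSON sidecar
#' (`pixel_size_um`, `z_step_um`, `n_pillars`, `expected_radius_um`) and
#' the ground-truth CSV next to each other.
#'
#' @param rendered result of [render_stack()].
#' @param dir output directory (created if needed).
#' @param stem file stem; outputs `<stem>.tiff`, `<stem>.json`,
#'   `<stem>_truth.csv`.
#' @return Invisibly, the three paths.
#' @export
write_synthetic_stack <- function(rendered, dir, stem = "stack") {
  stopifnot(is.list(rendered), inherits(rendered$stack, "image_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tif <- file.path(dir, paste0(stem, ".tiff"))
  side <- file.path(dir, paste0(stem, ".json"))
  tru <- file.path(dir, paste0(stem, "_truth.csv"))
  tiff::writeTIFF(rendered$stack$slices, tif, bits.per.sample = 16,
                  compression = "none")
  jsonlite::write_json(list(pixel_size_um = rendered$stack$pixel_size,
                            z_step_um = rendered$stack$z_step,
                            n_pillars = attr(rendered$stack, "n_pillars"),
                            expected_radius_um = attr(rendered$stack, "expected_radius_um")),
                       side, auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(rendered$truth), tru, row.names = FALSE)
  invisible(c(tiff = tif, sidecar = side, truth = tru))
}
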