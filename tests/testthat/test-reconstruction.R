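# A two-slice stack holding one ideal disk, built directly from the raster
# primitive (no renderer optics), for the symmetry checks.
single_disk_stack <- function(n = 65, cx = n / 2, cy = n / 2, r_px = 7,
                              pixel_size = 2) {
  disk <- pillarforce:::soft_disk_patch(n, n, cx, cy, r_px)
  image_stack(list(disk, disk), pixel_size_um = pixel_size, z_step_um = 4)
}

test_that("base-slice segmentation finds ring pillars at sub-pixel accuracy", {
  sc <- synthetic_scene(forces_nN = 0, noise_sigma = 0, seed = 3)
  rend <- render_stack(sc)
  det <- segment_base_slice(rend$stack, expected_radius_um = 14, n_expected = 12)
  expect_equal(nrow(det), 12)
  truth1 <- rend$truth[rend$truth$slice == 1, ]
  for (i in seq_len(12)) {
    dmin <- min(sqrt((truth1$x_um - det$x_um[i])^2 +
                       (truth1$y_um - det$y_um[i])^2))
    expect_lt(dmin, 0.5 * sc$pixel_size)      # within half a pixel
  }
  expect_true(all(det$energy > 0.8))
  expect_true(all(abs(det$radius_um - 14) < 3))
})

test_that("a blank first slice raises a detection-count error", {
  blank <- image_stack(list(matrix(0, 64, 64), matrix(0, 64, 64)),
                       pixel_size_um = 2, z_step_um = 4)
  expect_error(segment_base_slice(blank, 14, 12), "found 0")
})

test_that("a single centred noiseless disk is located at the image centre", {
  st <- single_disk_stack()
  det <- segment_base_slice(st, expected_radius_um = 14, n_expected = 1)
  expect_equal(det$x_um, 65, tolerance = 1e-6)   # 32.5 px * 2 um
  expect_equal(det$y_um, 65, tolerance = 1e-6)
})

test_that("propagation re-finds an unmoved disk to sub-pixel tolerance", {
  st <- single_disk_stack()
  prev <- list(x_um = 65, y_um = 65, radius_um = 14)
  det <- propagate_slice(prev, st$slices[[2]], pixel_size_um = 2)
  expect_true(det$valid)
  expect_lt(abs(det$x_um - 65), 0.1)
  expect_lt(abs(det$y_um - 65), 0.1)
})

test_that("propagation marks an empty search region invalid and tracking survives", {
  prev <- list(x_um = 65, y_um = 65, radius_um = 14)
  det <- propagate_slice(prev, matrix(0, 65, 65), pixel_size_um = 2)
  expect_false(det$valid)
  expect_identical(det$energy, 0)
  expect_identical(det$x_um, prev$x_um)   # carries last position forward
})

test_that("straight pillars are tracked with sub-pixel drift across all slices", {
  sc <- small_scene(forces_nN = 0, seed = 11)
  rend <- render_stack(sc)
  profs <- reconstruct_stack(rend$stack)
  for (p in profs) {
    expect_true(all(p$valid))
    drift <- sqrt((p$x_um - p$x_um[1])^2 + (p$y_um - p$y_um[1])^2)
    expect_lt(max(drift), 0.5 * sc$pixel_size)
    expect_lt(max(abs(p$d_um)), 0.5)            # no spurious deflection (um)
  }
})

test_that("bent pillars are tracked along all slices without identity switches", {
  sc <- small_scene(forces_nN = 300, seed = 12)  # ~20 um tip deflection
  rend <- render_stack(sc)
  profs <- reconstruct_stack(rend$stack)
  top_truth <- rend$truth[rend$truth$slice == sc$n_z, ]
  base_truth <- rend$truth[rend$truth$slice == 1, ]
  for (p in profs) {
    expect_true(all(p$valid))
    b <- attr(p, "base_um")
    k <- which.min((base_truth$x_um - b[1])^2 + (base_truth$y_um - b[2])^2)
    top_err <- sqrt((p$x_um[sc$n_z] - top_truth$x_um[k])^2 +
                      (p$y_um[sc$n_z] - top_truth$y_um[k])^2)
    expect_lt(top_err, 2)   # um; same pillar from base to top
  }
})

test_that("skeleton smoothing preserves straight lines, ignores zero-weight outliers, and interpolates cubics", {
  z <- (0:74) * 4
  straight <- rep(100, 75)
  sk <- smooth_skeleton(z, straight, straight)
  expect_equal(sk$x, straight, tolerance = 1e-8)
  # a 5-pixel outlier down-weighted to zero energy barely perturbs the fit
  x_out <- straight; x_out[40] <- 110
  en <- rep(1, 75); en[40] <- 0
  sk2 <- smooth_skeleton(z, x_out, x_out, energy = en)
  expect_lt(abs(sk2$x[40] - 100), 0.4)          # < 0.2 px at 2 um/px
  expect_true(sk2$imputed[40])
  # zero smoothing penalty reproduces a cubic skeleton exactly
  cub <- 50 + 0.1 * z - 1e-3 * z^2 + 1e-5 * z^3
  sk3 <- smooth_skeleton(z, cub, cub, df = 0)
  expect_equal(sk3$x, cub, tolerance = 1e-8)
  expect_error(smooth_skeleton(z[1:3], cub[1:3], cub[1:3]), "4 valid")
})

test_that("reconstruction recovers forward-model deflection curves", {
  sc <- small_scene(forces_nN = c(230, 230, 230, 230), seed = 21)
  rend <- render_stack(sc)
  profs <- reconstruct_stack(rend$stack)
  ab <- build_abacus(sc$geom, sc$mat, load_span = sc$loaded_span)
  rec <- match_recovery(profs, rend$truth, ab)
  expect_true(all(rec$rms_um < 1))
  # smoothed profiles of outward-bent pillars are monotone within 0.3 um
  for (p in profs) expect_true(all(diff(p$d_um) > -0.3))
})

test_that("reconstruction tolerates strong depth attenuation and blur", {
  sc <- small_scene(forces_nN = 230, attenuation_top = 0.5,
                    blur_sigma_top_um = 4, seed = 22)
  rend <- render_stack(sc)
  profs <- reconstruct_stack(rend$stack)
  ab <- build_abacus(sc$geom, sc$mat, load_span = sc$loaded_span)
  rec <- match_recovery(profs, rend$truth, ab)
  expect_true(all(rec$rms_um < 1.5))
})

test_that("tip displacements of a symmetric scene point radially outward", {
  sc <- small_scene(forces_nN = 250, seed = 23)
  rend <- render_stack(sc)
  profs <- reconstruct_stack(rend$stack)
  centre <- sc$image_size * sc$pixel_size / 2
  for (p in profs) {
    tip <- c(p$x_um[sc$n_z], p$y_um[sc$n_z]) - attr(p, "base_um")
    radial <- attr(p, "base_um") - centre
    ang <- acos(sum(tip * radial) /
                  (sqrt(sum(tip^2)) * sqrt(sum(radial^2)))) * 180 / pi
    expect_lt(ang, 15)
  }
})

test_that("detection energy decreases monotonically with added noise", {
  sc <- small_scene(forces_nN = 0, noise_sigma = 0, seed = 31)
  rend <- render_stack(sc)
  slice <- rend$stack$slices[[1]]
  truth1 <- rend$truth[rend$truth$slice == 1, ]
  prev <- list(x_um = truth1$x_um[1], y_um = truth1$y_um[1], radius_um = 14)
  energies <- withr::with_seed(5, {
    vapply(c(0, 0.05, 0.15, 0.3), function(s) {
      noisy <- pmin(pmax(slice + stats::rnorm(length(slice), sd = s), 0), 1)
      propagate_slice(prev, matrix(noisy, nrow(slice)), pixel_size_um = 2)$energy
    }, numeric(1))
  })
  expect_true(all(diff(energies) < 0))
})

test_that("stacks round-trip through TIFF + sidecar and profiles through CSV", {
  sc <- small_scene(forces_nN = 150, seed = 41)
  rend <- render_stack(sc)
  dir <- withr::local_tempdir()
  paths <- write_synthetic_stack(rend, dir, stem = "demo")
  st <- read_image_stack(paths[["tiff"]])
  expect_equal(st$n_z, sc$n_z)
  expect_equal(st$pixel_size, sc$pixel_size)
  expect_equal(attr(st, "n_pillars"), sc$n_pillars)
  # 16-bit quantization is applied at render time, so pixels round-trip exactly
  expect_equal(st$slices[[10]], rend$stack$slices[[10]], tolerance = 1e-9)
  profs <- reconstruct_stack(st)
  csv <- file.path(dir, "profiles.csv")
  write_profiles_csv(profs, csv)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), sc$n_pillars * sc$n_z)
  expect_true(all(c("pillar_id", "z_um", "d_um", "energy", "valid") %in% names(back)))
})
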