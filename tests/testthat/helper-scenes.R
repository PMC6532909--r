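# Shared fixtures: device-standard geometry/material and reduced-size
# synthetic scenes, plus a matcher from reconstructed profiles (ordered by
# detection angle) back to ground-truth pillar ids (ordered by ring angle).

std_geom <- function(d_um = 28) pillar_geometry(d = d_um * 1e-6, h = 300e-6)
std_mat <- function() beam_material()
std_load <- function(F_nN, s_um = 175) load_spec(F = F_nN * 1e-9, s = s_um * 1e-6)

# 4-pillar scene on a smaller raster: same optics and slice count as the
# full device, cheaper to render.
small_scene <- function(...) {
  synthetic_scene(n_pillars = 4, ring_radius_um = 120, image_size_px = 192, ...)
}

# For each reconstructed profile, find the ground-truth pillar whose base is
# nearest, and return a data.frame pairing estimates with true forces.
match_recovery <- function(profiles, truth, abacus) {
  base_truth <- truth[truth$slice == 1, ]
  rows <- lapply(profiles, function(p) {
    b <- attr(p, "base_um")
    k <- which.min((base_truth$x_um - b[1])^2 + (base_truth$y_um - b[2])^2)
    est <- estimate_force(p, abacus)
    tr <- truth[truth$pillar_id == base_truth$pillar_id[k], ]
    data.frame(pillar_id = base_truth$pillar_id[k],
               F_true_nN = base_truth$F_nN[k],
               F_best_nN = est$F_best * 1e9,
               F_refined_nN = est$F_refined * 1e9,
               rms_um = sqrt(mean((p$d_um - tr$defl_um)^2)),
               base_dist_um = sqrt(min((base_truth$x_um - b[1])^2 +
                                         (base_truth$y_um - b[2])^2)))
  })
  do.call(rbind, rows)
}
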