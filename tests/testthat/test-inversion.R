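test_that("abacus has the sweep's inclusive grid and scales linearly", {
  ab <- build_abacus(std_geom(), std_mat())
  expect_length(ab$force_grid, 101)     # 0-1000 nN in 10 nN steps
  curves <- abacus_curves(ab, c(0, 100e-9, 200e-9))
  expect_identical(curves[, 1], rep(0, length(ab$z_ref)))
  expect_equal(curves[, 3], 2 * curves[, 2], tolerance = 1e-14)
  expect_error(build_abacus(std_geom(), std_mat(), sweep_step = 0), "positive")
  expect_error(build_abacus(std_geom(), std_mat(), sweep_start = 1e-6,
                            sweep_stop = 0), "stop > start")
})

test_that("curve resampling is exact at nodes, on cubics, and refuses extrapolation", {
  z <- seq(0, 300, length.out = 40)
  y <- sin(z / 80)
  expect_equal(resample_curve(y, z, z), y, tolerance = 1e-13)
  cubic <- 1 + 2 * z - 0.01 * z^2 + 1e-4 * z^3
  zt <- seq(10, 290, length.out = 57)
  expect_equal(resample_curve(cubic, z, zt),
               1 + 2 * zt - 0.01 * zt^2 + 1e-4 * zt^3, tolerance = 1e-9)
  expect_error(resample_curve(y, z, c(-5, 100)), "extrapolate")
  # coarse 75-point resampling of the physical deflection curve stays
  # below a nanometre of the directly evaluated closed form
  geom <- std_geom(); mat <- std_mat()
  z_src <- seq(0, 300e-6, length.out = 75)
  z_tgt <- seq(0, 296e-6, by = 4e-6)
  approxed <- resample_curve(
    deflection_profile(geom, mat, std_load(230), z_src), z_src, z_tgt)
  direct <- deflection_profile(geom, mat, std_load(230), z_tgt)
  expect_lt(max(abs(approxed - direct)), 1e-9)
})

test_that("fit statistics implement SS_res, R2 and M", {
  d <- c(0.1, 0.4, 1.2, 2.5)
  perfect <- fit_metrics(d, d)
  expect_identical(perfect$ss_res, 0)
  expect_identical(perfect$r2, 1)
  expect_identical(perfect$m_shift, 0)
  # constant offset c: SS_res = n c^2, M = |c|
  off <- fit_metrics(d, d + 0.3)
  expect_equal(off$ss_res, 4 * 0.3^2, tolerance = 1e-14)
  expect_equal(off$m_shift, 0.3, tolerance = 1e-14)
  # 3-point worked example: d = (0,1,2), v = (0,1,4)
  ex <- fit_metrics(c(0, 1, 2), c(0, 1, 4))
  expect_identical(ex$ss_res, 4)
  expect_identical(ex$m_shift, 2)
  expect_identical(ex$r2, -1)          # SS_tot = 2
  # degenerate constant detected curve is flagged, not divided by zero
  deg <- fit_metrics(c(1, 1, 1), c(0, 1, 2))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$r2))
  expect_error(fit_metrics(1:3, 1:4), "equal length")
  expect_error(fit_metrics(1, 1), "2 slices")
})

test_that("grid minimum selection breaks ties toward the smaller force", {
  single <- data.frame(F = 5e-8, ss_res = 1)
  expect_identical(select_grid_minimum(single), 5e-8)
  tie <- data.frame(F = c(100e-9, 120e-9), ss_res = c(2, 2))
  expect_identical(select_grid_minimum(tie), 100e-9)
  Fg <- seq(0, 1e-6, by = 1e-8)
  convex <- data.frame(F = Fg, ss_res = (Fg - 4.3e-7)^2)
  expect_identical(select_grid_minimum(convex), 4.3e-7)
})

test_that("forward-model profiles are recovered exactly over the sweep", {
  geom <- std_geom(); mat <- std_mat()
  ab <- build_abacus(geom, mat)
  z <- seq(0, 296e-6, by = 4e-6)
  for (F_nN in c(10, 230, 480, 990)) {
    prof <- list(z = z, d = deflection_profile(geom, mat, std_load(F_nN), z))
    est <- estimate_force(prof, ab)
    expect_equal(est$F_best * 1e9, F_nN)
    expect_equal(est$F_refined * 1e9, F_nN, tolerance = 1e-6)
    expect_equal(est$metrics_at_best$r2, 1, tolerance = 1e-9)
    # the three criteria select the same candidate on noiseless profiles
    pc <- est$per_candidate
    expect_equal(which.min(pc$ss_res), which.max(pc$r2))
    expect_equal(which.min(pc$ss_res), which.min(pc$m_shift))
  }
})

test_that("off-grid forces fall on a neighbouring candidate with exact refinement", {
  geom <- std_geom(); mat <- std_mat()
  ab <- build_abacus(geom, mat)
  z <- seq(0, 296e-6, by = 4e-6)
  prof <- list(z = z, d = deflection_profile(geom, mat, std_load(235), z))
  est <- estimate_force(prof, ab)
  expect_true(min(abs(est$F_best * 1e9 - c(230, 240))) < 1e-6)
  expect_equal(est$F_refined * 1e9, 235, tolerance = 0.1)
  # sweep-to-continuum gap is bounded by half a grid step on clean profiles
  for (F_nN in c(103, 217.2, 764.9)) {
    p <- list(z = z, d = deflection_profile(geom, mat, std_load(F_nN), z))
    e <- estimate_force(p, ab)
    expect_lte(abs(e$F_best - e$F_refined) * 1e9, 5 + 1e-9)
  }
})

test_that("degenerate profiles are flagged instead of fitted", {
  ab <- build_abacus(std_geom(), std_mat())
  z <- seq(0, 296e-6, by = 4e-6)
  est <- estimate_force(list(z = z, d = rep(0, length(z))), ab)
  expect_true(est$degenerate)
  expect_true(is.na(est$F_best))
  expect_error(estimate_force(list(z = z[1], d = 0), ab), "2 valid slices")
})

test_that("noisy-slice Monte-Carlo recovery is unbiased with sub-grid-step spread", {
  geom <- std_geom(); mat <- std_mat()
  ab <- build_abacus(geom, mat)
  z <- seq(0, 296e-6, by = 4e-6)
  u <- resample_curve(ab$unit_profile, ab$z_ref, z)
  d0 <- deflection_profile(geom, mat, std_load(230), z)
  sigma <- 0.5e-6                       # per-slice centre noise, 0.5 um
  est <- withr::with_seed(424, {
    vapply(seq_len(200), function(r) {
      d <- d0 + stats::rnorm(length(z), sd = sigma)
      sum(d * u) / sum(u^2)             # exact LS refinement under linearity
    }, numeric(1))
  })
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) * 1e9 - 230), 3 * se * 1e9)  # unbiased
  expect_lt(stats::sd(est) * 1e9, 10)                  # below one grid step
})

test_that("estimate tables and abacus CSV round-trip through disk", {
  geom <- std_geom(); mat <- std_mat()
  ab <- build_abacus(geom, mat)
  z <- seq(0, 296e-6, by = 4e-6)
  ests <- lapply(c(100, 300), function(F_nN)
    estimate_force(list(z = z, d = deflection_profile(geom, mat,
                                                      std_load(F_nN), z)), ab))
  tab <- estimates_table(ests, device_id = "dev1", day = 4)
  expect_equal(tab$F_best_nN, c(100, 300))
  expect_false(any(tab$degenerate))
  path <- withr::local_tempfile(fileext = ".csv")
  write_abacus_csv(ab, path)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(back), length(ab$z_ref))
  expect_equal(ncol(back), 1 + 101)
  expect_equal(back[["F_230_nN"]],
               230e-9 * ab$unit_profile * 1e6, tolerance = 1e-9)
})
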