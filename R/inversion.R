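#' Build an abacus of simulated deflection curves over a force sweep
#'
#' The abacus is the family of simulated pillar deflection curves, one per
#' candidate force on an inclusive sweep grid (by default 0 to 1000 nN in
#' 10 nN steps, 101 candidates). Because the beam model is exactly linear in
#' the applied force, only the deflection per unit force is computed and
#' stored; the curve for any candidate is the unit profile scaled by that
#' force.
#'
#' @param geom a [pillar_geometry()].
#' @param mat a [beam_material()].
#' @param load_span loaded span from the pillar top (m); default 175 um.
#' @param sweep_start,sweep_stop,sweep_step force sweep bounds and step (N);
#'   defaults 0, 1e-6, 1e-8 (0-1000 nN, step 10 nN).
#' @param z_ref reference heights (m) on which the unit profile is stored;
#'   defaults to 75 evenly spaced slices from base to top.
#' @return An object of class `abacus` with fields `force_grid` (N),
#'   `z_ref` (m) and `unit_profile` (m deflection per N).
#' @examples
#' ab <- build_abacus(pillar_geometry(28e-6, 300e-6), beam_material())
#' length(ab$force_grid)  # 101
#' @export
build_abacus <- function(geom, mat, load_span = 175e-6,
                         sweep_start = 0, sweep_stop = 1e-6, sweep_step = 1e-8,
                         z_ref = NULL) {
  stopifnot(inherits(geom, "pillar_geometry"), inherits(mat, "beam_material"))
  if (sweep_step <= 0) stop("sweep step must be positive", call. = FALSE)
  if (sweep_stop <= sweep_start || sweep_start < 0)
    stop("force sweep requires stop > start >= 0", call. = FALSE)
  if (is.null(z_ref)) z_ref <- seq(0, geom$h, length.out = 75)
  force_grid <- seq(sweep_start, sweep_stop, by = sweep_step)
  unit <- deflection_profile(geom, mat, load_spec(F = 1, s = load_span), z_ref)
  structure(list(force_grid = force_grid, z_ref = z_ref, unit_profile = unit,
                 geom = geom, mat = mat, load_span = load_span),
            class = "abacus")
}

#' Expand abacus curves for chosen candidate forces
#'
#' @param abacus an [build_abacus()] object.
#' @param forces forces (N) at which to expand; defaults to the whole grid.
#' @return Matrix with one column per force, rows on `abacus$z_ref`.
#' @export
abacus_curves <- function(abacus, forces = abacus$force_grid) {
  stopifnot(inherits(abacus, "abacus"))
  outer(abacus$unit_profile, forces)
}

#' Re-discretize a deflection curve onto a new height grid
#'
#' Cubic-spline interpolation of a simulated (or measured) curve onto the
#' grid of the experimental slices, so that simulated and detected
#' displacements can be compared slice by slice. The spline is exact at the
#' source nodes and reproduces polynomials up to cubic degree. Extrapolation
#' outside the source span is refused rather than silently performed.
#'
#' @param curve displacements on `source_z`.
#' @param source_z strictly increasing source heights.
#' @param target_z heights to interpolate to; must lie within the span of
#'   `source_z`.
#' @return Displacements on `target_z`.
#' @export
resample_curve <- function(curve, source_z, target_z) {
  stopifnot(is.numeric(curve), is.numeric(source_z), is.numeric(target_z),
            length(curve) == length(source_z))
  if (any(diff(source_z) <= 0))
    stop("source grid must be strictly increasing", call. = FALSE)
  eps <- 1e-9 * diff(range(source_z))
  if (min(target_z) < min(source_z) - eps || max(target_z) > max(source_z) + eps)
    stop("target grid lies outside the source span; refusing to extrapolate",
         call. = FALSE)
  stats::splinefun(source_z, curve, method = "fmm")(target_z)
}

#' Goodness-of-fit statistics between detected and simulated deflections
#'
#' Computes the three statistics used to match an experimental deflection
#' curve against a simulated candidate, with `d_i` the detected and `v_i`
#' the simulated displacement at slice `i`:
#' the sum of squared residuals `SS_res = sum (d_i - v_i)^2`, the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot` (with
#' `SS_tot = sum (d_i - mean(d))^2`), and the largest per-slice shift
#' `M = max |d_i - v_i|`. A constant detected curve has `SS_tot = 0`; the
#' result is then flagged degenerate and `R^2` is `NA` rather than a
#' division by zero.
#'
#' @param detected detected displacements `d_i`, one per slice (>= 2).
#' @param simulated simulated displacements `v_i`, same length.
#' @return A list of class `fit_result`: `ss_res`, `r2`, `m_shift`,
#'   `degenerate`.
#' @examples
#' fit_metrics(c(0, 1, 2), c(0, 1, 4))  # SS_res 4, R2 -1, M 2
#' @export
fit_metrics <- function(detected, simulated) {
  stopifnot(is.numeric(detected), is.numeric(simulated))
  if (length(detected) != length(simulated))
    stop("detected and simulated curves must have equal length", call. = FALSE)
  if (length(detected) < 2)
    stop("at least 2 slices are required", call. = FALSE)
  res <- detected - simulated
  ss_res <- sum(res^2)
  ss_tot <- sum((detected - mean(detected))^2)
  degenerate <- ss_tot == 0
  structure(list(ss_res = ss_res,
                 r2 = if (degenerate) NA_real_ else 1 - ss_res / ss_tot,
                 m_shift = max(abs(res)),
                 degenerate = degenerate),
            class = "fit_result")
}

#' Pick the best-fitting force on the sweep grid
#'
#' Argmin of `SS_res` over the per-candidate fit table; since `SS_tot` is
#' fixed by the detected curve, this is equivalently the argmax of `R^2`.
#' Exact ties are broken toward the smaller force (the conservative
#' estimate).
#'
#' @param per_candidate data frame with columns `F` (N, increasing) and
#'   `ss_res`.
#' @return The selected force (N).
#' @export
select_grid_minimum <- function(per_candidate) {
  stopifnot(is.data.frame(per_candidate), nrow(per_candidate) >= 1,
            all(c("F", "ss_res") %in% names(per_candidate)))
  ord <- order(per_candidate$F)
  pc <- per_candidate[ord, ]
  pc$F[which.min(pc$ss_res)]  # which.min takes the first of tied minima
}

#' Estimate the force applied to one pillar from its deflection profile
#'
#' Scores every candidate force of the abacus against the detected profile
#' with [fit_metrics()] and selects the best grid candidate via
#' [select_grid_minimum()]. In addition to the grid estimate, the exact
#' continuous least-squares force is returned: by linearity of the forward
#' model the simulated curve at force `F` is `F u_i` with `u_i` the
#' unit-force deflection, so the residual sum of squares is minimized at
#' `F_refined = sum(d_i u_i) / sum(u_i^2)`.
#'
#' The abacus unit profile is resampled onto the profile's slice heights
#' with [resample_curve()]; only slices marked valid enter the fit, and
#' their count is recorded. A constant detected curve (for example an
#' undeflected pillar) yields a degenerate estimate with no selected force.
#'
#' @param profile either a `pillar_profile` from [reconstruct_stack()]
#'   (heights and deflections in um, converted internally) or a list with
#'   fields `z` and `d` in metres and optionally a logical `valid` mask.
#' @param abacus an [build_abacus()] object whose `z_ref` spans the profile
#'   heights.
#' @return An object of class `force_estimate`: `F_best` and `F_refined`
#'   (N; `NA` when degenerate), `metrics_at_best` ([fit_metrics()] result),
#'   `per_candidate` (data frame `F`, `ss_res`, `r2`, `m_shift`),
#'   `n_slices`, `degenerate`.
#' @export
estimate_force <- function(profile, abacus) {
  stopifnot(inherits(abacus, "abacus"))
  if (inherits(profile, "pillar_profile")) {
    z <- profile$z_um * 1e-6
    d <- profile$d_um * 1e-6
    valid <- profile$valid
  } else {
    z <- profile$z
    d <- profile$d
    valid <- if (is.null(profile$valid)) rep(TRUE, length(z)) else profile$valid
  }
  stopifnot(length(z) == length(d))
  z <- z[valid]; d <- d[valid]
  if (length(z) < 2)
    stop("at least 2 valid slices are required to estimate a force", call. = FALSE)
  u <- resample_curve(abacus$unit_profile, abacus$z_ref, z)

  grid <- abacus$force_grid
  per <- data.frame(F = grid, ss_res = NA_real_, r2 = NA_real_, m_shift = NA_real_)
  degenerate <- sum((d - mean(d))^2) == 0 || sum(u^2) == 0
  for (k in seq_along(grid)) {
    fm <- fit_metrics(d, grid[k] * u)
    per$ss_res[k] <- fm$ss_res
    per$r2[k] <- fm$r2
    per$m_shift[k] <- fm$m_shift
  }
  if (degenerate) {
    return(structure(list(F_best = NA_real_, F_refined = NA_real_,
                          metrics_at_best = NULL, per_candidate = per,
                          n_slices = length(z), degenerate = TRUE),
                     class = "force_estimate"))
  }
  F_best <- select_grid_minimum(per)
  F_refined <- sum(d * u) / sum(u^2)
  structure(list(F_best = F_best,
                 F_refined = F_refined,
                 metrics_at_best = fit_metrics(d, F_best * u),
                 per_candidate = per,
                 n_slices = length(z),
                 degenerate = FALSE),
            class = "force_estimate")
}

#' @export
print.force_estimate <- function(x, ...) {
  if (x$degenerate) {
    cat("Force estimate: degenerate profile (no deflection signal),",
        x$n_slices, "slices\n")
  } else {
    cat(sprintf("Force estimate: F_best = %.0f nN (grid), F_refined = %.1f nN (LS)\n",
                x$F_best * 1e9, x$F_refined * 1e9))
    cat(sprintf("  fit at best: SS_res = %.3g um^2, R2 = %.4f, M = %.2f um over %d slices\n",
                x$metrics_at_best$ss_res * 1e12, x$metrics_at_best$r2,
                x$metrics_at_best$m_shift * 1e6, x$n_slices))
  }
  invisible(x)
}

#' Write an abacus to CSV
#'
#' One row per reference height (um), one column per candidate force (nN);
#' the header carries the force in nN.
#'
#' @param abacus an [build_abacus()] object.
#' @param path output CSV path.
#' @export
write_abacus_csv <- function(abacus, path) {
  stopifnot(inherits(abacus, "abacus"))
  m <- abacus_curves(abacus) * 1e6
  df <- data.frame(z_um = abacus$z_ref * 1e6, m, check.names = FALSE)
  names(df)[-1] <- sprintf("F_%g_nN", abacus$force_grid * 1e9)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Collect force estimates into a result table
#'
#' @param estimates list of [estimate_force()] results.
#' @param device_id,pillar_id,day identifying columns recycled across rows.
#' @return Data frame with columns `device_id`, `pillar_id`, `day`,
#'   `F_best_nN`, `F_refined_nN`, `SS_res`, `R2`, `M`, `n_slices`,
#'   `degenerate`.
#' @export
estimates_table <- function(estimates, device_id = "device", pillar_id = NULL,
                            day = NA) {
  stopifnot(is.list(estimates), length(estimates) >= 1)
  if (is.null(pillar_id)) pillar_id <- seq_along(estimates)
  rows <- lapply(seq_along(estimates), function(i) {
    e <- estimates[[i]]
    data.frame(device_id = device_id[[min(i, length(device_id))]],
               pillar_id = pillar_id[[i]],
               day = day,
               F_best_nN = if (e$degenerate) NA_real_ else e$F_best * 1e9,
               F_refined_nN = if (e$degenerate) NA_real_ else e$F_refined * 1e9,
               SS_res = if (e$degenerate) NA_real_ else e$metrics_at_best$ss_res,
               R2 = if (e$degenerate) NA_real_ else e$metrics_at_best$r2,
               M = if (e$degenerate) NA_real_ else e$metrics_at_best$m_shift,
               n_slices = e$n_slices,
               degenerate = e$degenerate)
  })
  do.call(rbind, rows)
}
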