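#' Summarize per-pillar force estimates
#'
#' Aggregates a table of per-pillar force estimates into group summaries:
#' arithmetic mean, sample standard deviation (`n - 1` denominator) and
#' counts. Degenerate estimates (pillars with no deflection signal) are
#' excluded from the statistics but counted. With a single usable value the
#' SD is reported `NA`.
#'
#' @param forces data frame with at least a force column `F_nN` and the
#'   grouping columns named in `by`; an optional logical `degenerate`
#'   column marks excluded rows.
#' @param by character vector of grouping column names, e.g. `"device_id"`
#'   or `"K_nN_um"`; `NULL` summarizes the whole table as one group.
#' @return Data frame with the grouping columns plus `mean_nN`, `sd_nN`,
#'   `n`, `n_degenerate`.
#' @examples
#' df <- data.frame(device_id = "d1", F_nN = c(100, 300))
#' summarize_forces(df, by = "device_id")  # mean 200, sd ~141.4
#' @export
summarize_forces <- function(forces, by = "device_id") {
  stopifnot(is.data.frame(forces), "F_nN" %in% names(forces))
  if (is.null(forces$degenerate)) forces$degenerate <- FALSE
  forces$degenerate[is.na(forces$F_nN)] <- TRUE
  if (is.null(by)) {
    forces$.all <- "all"
    by <- ".all"
  }
  stopifnot(all(by %in% names(forces)))
  key <- interaction(forces[by], drop = TRUE, lex.order = TRUE)
  out <- lapply(levels(key), function(lv) {
    g <- forces[key == lv, , drop = FALSE]
    use <- g$F_nN[!g$degenerate]
    cbind(g[1, by, drop = FALSE],
          data.frame(mean_nN = if (length(use)) mean(use) else NA_real_,
                     sd_nN = if (length(use) >= 2) stats::sd(use) else NA_real_,
                     n = length(use),
                     n_degenerate = sum(g$degenerate)))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[out$n == 0, "mean_nN"] <- NA_real_
  out
}

#' Rate of force change over time
#'
#' Ordinary least-squares slope of force versus time, reported in nN/hr
#' with its standard error — the growth-rate statistic of the temporal
#' force analysis. With exactly two points the slope is the finite
#' difference and the standard error is `NA`.
#'
#' @param force_nN forces (nN), typically per-day means.
#' @param time_hr observation times (hours); day `k` of culture maps to
#'   `24 k` hours.
#' @return List with `rate_nN_hr`, `se_nN_hr`, `intercept_nN`, `n`.
#' @examples
#' force_rate(c(121, 230), c(24, 96))  # (230-121)/72 ~ 1.51 nN/hr
#' @export
force_rate <- function(force_nN, time_hr) {
  stopifnot(is.numeric(force_nN), is.numeric(time_hr),
            length(force_nN) == length(time_hr))
  keep <- is.finite(force_nN) & is.finite(time_hr)
  force_nN <- force_nN[keep]; time_hr <- time_hr[keep]
  if (length(force_nN) < 2)
    stop("at least 2 time points are required for a rate", call. = FALSE)
  fit <- stats::lm(force_nN ~ time_hr)
  # summary.lm warns on an essentially perfect fit (e.g. constant forces);
  # the slope and SE are still well defined
  cf <- suppressWarnings(summary(fit))$coefficients
  list(rate_nN_hr = unname(cf["time_hr", "Estimate"]),
       se_nN_hr = if (length(force_nN) > 2) unname(cf["time_hr", "Std. Error"]) else NA_real_,
       intercept_nN = unname(cf["(Intercept)", "Estimate"]),
       n = length(force_nN))
}

#' Two-sample comparison of force groups
#'
#' Two-tailed Student's t test between two groups of forces (pooled
#' variance by default, Welch via `welch = TRUE`), with significance stars
#' following the figure convention: `*` for p < 0.05, `***` for p < 0.001,
#' `****` for p < 0.0001, `ns` otherwise. No multiple-testing correction is
#' applied; stars are per-pair.
#'
#' @param group_a,group_b numeric force vectors (nN), each of length >= 2.
#' @param welch logical; use the Welch unequal-variance test.
#' @return List with `t`, `df`, `p`, `stars`, `mean_a`, `mean_b`.
#' @export
compare_days <- function(group_a, group_b, welch = FALSE) {
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations", call. = FALSE)
  ht <- stats::t.test(group_a, group_b, var.equal = !welch,
                      alternative = "two.sided", conf.level = 0.95)
  p <- ht$p.value
  stars <- if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.05) "*" else "ns"
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = p,
       stars = stars, mean_a = mean(group_a), mean_b = mean(group_b))
}

#' Simulate a multi-device force study
#'
#' Draws per-pillar forces from normal distributions with prescribed
#' per-day means and SDs for one device stiffness group — the sampling
#' model used to demonstrate study-level statistics (stiffness ordering,
#' temporal increase) without image data. Pillars are organized into
#' devices so both units of analysis (pillar and device) can be compared.
#'
#' @param K_nN_um device spring constant label (nN/um).
#' @param days vector of observation days.
#' @param n_devices devices per day (recycled to `length(days)`).
#' @param pillars_per_device pillars measured per device.
#' @param mean_nN per-day mean force (nN), recycled.
#' @param sd_nN per-day SD of pillar forces (nN), recycled.
#' @param seed RNG seed.
#' @return Data frame: `device_id`, `pillar_id`, `day`, `K_nN_um`, `F_nN`.
#' @export
simulate_force_study <- function(K_nN_um, days, n_devices,
                                 pillars_per_device = 16,
                                 mean_nN, sd_nN = 100, seed = 1) {
  stopifnot(length(days) >= 1)
  n_devices <- rep_len(n_devices, length(days))
  mean_nN <- rep_len(mean_nN, length(days))
  sd_nN <- rep_len(sd_nN, length(days))
  withr::with_seed(seed, {
    rows <- lapply(seq_along(days), function(i) {
      ndev <- n_devices[i]
      data.frame(
        device_id = sprintf("K%g_day%g_dev%02d", K_nN_um, days[i],
                            rep(seq_len(ndev), each = pillars_per_device)),
        pillar_id = rep(seq_len(pillars_per_device), times = ndev),
        day = days[i],
        K_nN_um = K_nN_um,
        F_nN = stats::rnorm(ndev * pillars_per_device,
                            mean = mean_nN[i], sd = sd_nN[i]))
    })
    do.call(rbind, rows)
  })
}

#' Plot deflection profiles against the best-fit abacus curves
#'
#' Base-graphics diagnostic: detected deflection per slice with the
#' selected simulated curve overlaid, one panel per pillar.
#'
#' @param profiles `pillar_profiles` from [reconstruct_stack()].
#' @param estimates optional list of [estimate_force()] results (same
#'   order) to overlay best-fit curves.
#' @param abacus the abacus used for the estimates (needed for overlays).
#' @param ... passed to [graphics::plot()].
#' @export
plot_profiles <- function(profiles, estimates = NULL, abacus = NULL, ...) {
  stopifnot(inherits(profiles, "pillar_profiles"))
  np <- length(profiles)
  mf <- grDevices::n2mfrow(np)
  old <- graphics::par(mfrow = mf, mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (i in seq_len(np)) {
    p <- profiles[[i]]
    graphics::plot(p$z_um, p$d_um, pch = 16, cex = 0.5,
                   xlab = "height z (um)", ylab = "deflection (um)",
                   main = sprintf("pillar %d", attr(p, "pillar_id")), ...)
    if (!is.null(estimates) && !is.null(abacus) && !estimates[[i]]$degenerate) {
      zz <- seq(min(p$z_um), max(p$z_um), length.out = 200)
      u <- resample_curve(abacus$unit_profile, abacus$z_ref, zz * 1e-6)
      graphics::lines(zz, estimates[[i]]$F_best * u * 1e6, col = "blue")
    }
  }
  invisible(NULL)
}
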