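#' Stress from forces and geometry
#'
#' \eqn{\sigma_i = F_i / A}, with the exact unit identity
#' 1 uN / 1 um^2 = 1 MPa. The initial cross-sectional area is used
#' throughout (constant-area assumption).
#'
#' @param forces_uN Numeric vector of forces (uN).
#' @param geom A [specimen_geometry()].
#' @return Stress vector in MPa.
#' @export
stress_series <- function(forces_uN, geom) {
  A <- cross_section_area(geom)
  if (!is.finite(A) || A <= 0) {
    stop_microext("cross-sectional area must be > 0.",
                  "microext_invalid_geometry")
  }
  forces_uN / A
}

#' Assemble a stress-strain curve
#'
#' @param forces_uN Per-step forces (uN).
#' @param strain_pct Per-step strain (percent), landmark-based by default
#'   in the full pipeline.
#' @param geom A [specimen_geometry()].
#' @param step Optional step indices.
#' @return A `stress_strain_curve` tibble: `step`, `strain_pct`,
#'   `stress_MPa`.
#' @export
stress_strain_curve <- function(forces_uN, strain_pct, geom, step = NULL) {
  stopifnot(length(forces_uN) == length(strain_pct))
  out <- tibble(step = step %||% seq_along(forces_uN),
                strain_pct = strain_pct,
                stress_MPa = stress_series(forces_uN, geom))
  class(out) <- c("stress_strain_curve", class(out))
  out
}

#' Select the linear region of a stress-strain curve
#'
#' Finds the contiguous window of `span_steps` steps maximizing the
#' linear-fit R^2, which keeps the window clear of the initial toe
#' (settling kinks at the start of stretching) and of the softening that
#' precedes rupture; ties are broken by the earliest start. Warns when
#' the selected region extends beyond 20% strain, outside the range
#' normally analysed elastically.
#'
#' @param curve A [stress_strain_curve()].
#' @param span_steps Window length in steps (default 50).
#' @return A list with `start`, `end` (row indices) and `r_squared`.
#' @export
select_linear_region <- function(curve, span_steps = 50) {
  n <- nrow(curve)
  if (n < span_steps) {
    stop_microext(sprintf("curve has %d steps, shorter than span %d.",
                          n, span_steps),
                  "microext_region_error")
  }
  best <- list(start = 1L, r2 = -Inf)
  for (s in seq_len(n - span_steps + 1L)) {
    idx <- s:(s + span_steps - 1L)
    x <- curve$strain_pct[idx]; y <- curve$stress_MPa[idx]
    if (sd(x) == 0 || sd(y) == 0) next
    r2 <- cor(x, y)^2
    if (r2 > best$r2 + 1e-12) best <- list(start = s, r2 = r2)
  }
  if (!is.finite(best$r2)) {
    stop_microext("no window with non-degenerate variation found.",
                  "microext_region_error")
  }
  end <- best$start + span_steps - 1L
  if (max(curve$strain_pct[best$start:end]) > 20) {
    warn("selected linear region extends beyond 20% strain; elastic analysis is normally limited to below 10-20%.")
  }
  list(start = best$start, end = end, r_squared = best$r2)
}

#' Young's modulus over a region of the curve
#'
#' By default the two-point definition \eqn{E = \Delta\sigma /
#' \Delta\varepsilon} over the region endpoints, with strain as a
#' fraction (the curve stores percent); `method = "ls"` uses the
#' least-squares slope instead.
#'
#' @param curve A [stress_strain_curve()].
#' @param region Region from [select_linear_region()]; default the whole
#'   curve.
#' @param method `"endpoints"` (default) or `"ls"`.
#' @return Modulus in MPa.
#' @export
youngs_modulus <- function(curve, region = NULL,
                           method = c("endpoints", "ls")) {
  method <- match.arg(method)
  region <- region %||% list(start = 1L, end = nrow(curve))
  idx <- region$start:region$end
  eps <- curve$strain_pct[idx] / 100
  sig <- curve$stress_MPa[idx]
  if (method == "endpoints") {
    d_eps <- eps[length(eps)] - eps[1]
    if (d_eps <= 0) {
      stop_microext("zero or negative strain increment over the region.",
                    "microext_invalid_region")
    }
    (sig[length(sig)] - sig[1]) / d_eps
  } else {
    unname(coef(lm(sig ~ eps))[2])
  }
}

#' Detect rupture as a sudden force drop
#'
#' The first step at which the force falls by at least `drop_frac`
#' relative to the running maximum.
#'
#' @param forces_uN Per-step forces.
#' @param drop_frac Relative drop that counts as rupture (default 0.5).
#' @return Step index of the drop, or `NA_integer_` when absent.
#' @export
detect_rupture <- function(forces_uN, drop_frac = 0.5) {
  if (length(forces_uN) < 2) return(NA_integer_)
  run_max <- cummax(forces_uN)
  hit <- which(forces_uN <= (1 - drop_frac) * run_max & run_max > 0)
  hit <- hit[hit > 1]
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Ultimate stress at rupture
#'
#' Maximum force before the detected drop, divided by the initial
#' cross-sectional area.
#'
#' @param forces_uN Per-step forces.
#' @param geom A [specimen_geometry()].
#' @param drop_frac Passed to [detect_rupture()].
#' @param run_to_break Treat the run as ending at rupture even when no
#'   drop is detected (uses the overall maximum).
#' @return Stress in MPa, or `NA` when no rupture and not flagged.
#' @export
ultimate_stress <- function(forces_uN, geom, drop_frac = 0.5,
                            run_to_break = FALSE) {
  r <- detect_rupture(forces_uN, drop_frac)
  if (is.na(r)) {
    if (!run_to_break) return(NA_real_)
    return(max(stress_series(forces_uN, geom)))
  }
  max(stress_series(forces_uN[seq_len(r - 1L)], geom))
}

#' Onset of plastic deformation (yield)
#'
#' Extrapolates the linear fit of the selected elastic region and flags
#' the first later step whose stress falls below the extrapolation by
#' more than `tolerance_frac` (relative). With `tolerance_frac = 0`, the
#' first numerical wiggle triggers (degenerate but documented).
#'
#' @param curve A [stress_strain_curve()].
#' @param region Linear region from [select_linear_region()].
#' @param tolerance_frac Relative deviation tolerance (default 5%).
#' @return A list with `step` (row index) and `yield_stress_MPa`, or
#'   values `NA` when no deviation is found.
#' @export
yield_onset <- function(curve, region, tolerance_frac = 0.05) {
  idx <- region$start:region$end
  fit <- lm(stress_MPa ~ strain_pct, data = curve[idx, ])
  after <- which(seq_len(nrow(curve)) > region$end)
  if (length(after) == 0) {
    return(list(step = NA_integer_, yield_stress_MPa = NA_real_))
  }
  pred <- coef(fit)[1] + coef(fit)[2] * curve$strain_pct[after]
  dev_ok <- pred > 0
  rel_dev <- (pred - curve$stress_MPa[after]) / pmax(pred, .Machine$double.eps)
  hit <- which(rel_dev > tolerance_frac & dev_ok)
  if (length(hit) == 0) {
    return(list(step = NA_integer_, yield_stress_MPa = NA_real_))
  }
  k <- after[hit[1]]
  list(step = k, yield_stress_MPa = curve$stress_MPa[k])
}

#' Windowed displacement rates (creep profile)
#'
#' Displacement rates for the landmark and grip pathways over
#' non-overlapping windows anchored at the start of the experiment
#' (default 300 s), as used to compare tissue creep with actuator
#' motion: each window's rate is (end - start) / window, with positions
#' linearly interpolated at the window boundaries.
#'
#' @param positions A data frame with columns `time_s`, `landmark_um`,
#'   `grip_um`.
#' @param window_s Window length in seconds (default 300).
#' @return A `creep_profile` tibble: `window`, `t_start_s`, `t_end_s`,
#'   `landmark_rate_um_per_s`, `grip_rate_um_per_s`.
#' @export
creep_rates <- function(positions, window_s = 300) {
  if (window_s <= 0) {
    stop_microext("`window_s` must be > 0.", "microext_invalid_window")
  }
  t <- positions$time_s
  duration <- max(t) - min(t)
  if (duration < window_s) {
    stop_microext("experiment shorter than one window.",
                  "microext_invalid_window")
  }
  n_win <- floor(duration / window_s)
  t0 <- min(t)
  at <- function(col, tt) approx(t, positions[[col]], xout = tt)$y
  out <- purrr::map_dfr(seq_len(n_win), function(w) {
    a <- t0 + (w - 1) * window_s
    b <- t0 + w * window_s
    tibble(window = w, t_start_s = a, t_end_s = b,
           landmark_rate_um_per_s = (at("landmark_um", b) - at("landmark_um", a)) / window_s,
           grip_rate_um_per_s = (at("grip_um", b) - at("grip_um", a)) / window_s)
  })
  class(out) <- c("creep_profile", class(out))
  out
}

#' Diagnose grip slippage from the two strain pathways
#'
#' Slip strain is the grip-pathway strain minus the landmark-pathway
#' strain. The run is called `"slip-dominated"` when, at the end of the
#' evaluated span, more of the apparent (grip) strain is slip than true
#' tissue strain; physically impossible negative slip beyond
#' `noise_tolerance_pp` triggers a data-inconsistency warning.
#'
#' @param series A [strain_series()] tibble.
#' @param noise_tolerance_pp Tolerated negative slip (percentage points).
#' @return A list with `per_step` (the series with slip) and `verdict`
#'   (`"slip-dominated"` or `"none"`).
#' @export
slippage_diagnosis <- function(series, noise_tolerance_pp = 0.5) {
  stopifnot(all(c("landmark_strain_pct", "grip_strain_pct") %in%
                  names(series)))
  slip <- series$grip_strain_pct - series$landmark_strain_pct
  if (any(slip < -noise_tolerance_pp)) {
    warn("negative slip strain beyond noise tolerance: landmark strain exceeds grip strain (check scale or tracking).")
  }
  last <- nrow(series)
  verdict <- if (slip[last] > series$landmark_strain_pct[last]) {
    "slip-dominated"
  } else {
    "none"
  }
  out <- series
  out$slip_strain_pct <- slip
  list(per_step = out, verdict = verdict)
}

#' Summarize the mechanics of a tensile run
#'
#' Bundles the derived scalar results: Young's modulus over the selected
#' linear region, ultimate stress and rupture step, and yield onset.
#'
#' @param curve A [stress_strain_curve()].
#' @param forces_uN The per-step forces the curve was built from.
#' @param geom A [specimen_geometry()].
#' @param span_steps Linear-region span (default `min(50, n - 1)`).
#' @param drop_frac,tolerance_frac Rupture and yield settings.
#' @return A `mechanical_summary` object; see [tidy()] and [glance()]
#'   methods.
#' @export
mechanical_summary <- function(curve, forces_uN, geom,
                               span_steps = NULL, drop_frac = 0.5,
                               tolerance_frac = 0.05) {
  rupture <- detect_rupture(forces_uN, drop_frac)
  n_use <- if (is.na(rupture)) nrow(curve) else rupture - 1L
  span_steps <- span_steps %||% min(50L, n_use - 1L)
  region <- select_linear_region(curve[seq_len(n_use), ], span_steps)
  E <- youngs_modulus(curve, region)
  yield <- yield_onset(curve[seq_len(n_use), ], region, tolerance_frac)
  structure(
    list(youngs_modulus_MPa = E,
         linear_region = region,
         ultimate_stress_MPa = ultimate_stress(forces_uN, geom, drop_frac,
                                               run_to_break = !is.na(rupture)),
         rupture_step = rupture,
         yield_onset_step = yield$step,
         yield_stress_MPa = yield$yield_stress_MPa,
         n_steps = nrow(curve)),
    class = "mechanical_summary"
  )
}

#' @export
print.mechanical_summary <- function(x, ...) {
  cat(sprintf("<mechanical_summary> E = %.2f MPa (steps %d-%d, R^2 = %.4f)\n",
              x$youngs_modulus_MPa, x$linear_region$start,
              x$linear_region$end, x$linear_region$r_squared))
  if (!is.na(x$rupture_step)) {
    cat(sprintf("  rupture at step %d, ultimate stress %.2f MPa\n",
                x$rupture_step, x$ultimate_stress_MPa))
  }
  if (!is.na(x$yield_onset_step)) {
    cat(sprintf("  yield onset at step %d, %.2f MPa\n",
                x$yield_onset_step, x$yield_stress_MPa))
  }
  invisible(x)
}

#' Tidy a mechanical summary
#'
#' @param x A `mechanical_summary`.
#' @param ... Unused.
#' @return One row per derived quantity: `quantity`, `value`, `unit`.
#' @export
tidy.mechanical_summary <- function(x, ...) {
  tibble(
    quantity = c("youngs_modulus", "ultimate_stress", "yield_stress"),
    value = c(x$youngs_modulus_MPa, x$ultimate_stress_MPa,
              x$yield_stress_MPa),
    unit = "MPa"
  )
}

#' One-row overview of a mechanical summary
#'
#' @param x A `mechanical_summary`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mechanical_summary <- function(x, ...) {
  tibble(
    youngs_modulus_MPa = x$youngs_modulus_MPa,
    ultimate_stress_MPa = x$ultimate_stress_MPa,
    yield_stress_MPa = x$yield_stress_MPa,
    rupture_step = x$rupture_step,
    yield_onset_step = x$yield_onset_step,
    linear_start = x$linear_region$start,
    linear_end = x$linear_region$end,
    linear_r_squared = x$linear_region$r_squared,
    n_steps = x$n_steps
  )
}
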