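#' Convert a reference weight to force
#'
#' \eqn{F = m g}; 1 g is ~9.806 mN. The standard-gravity default can be
#' overridden (workflows in the field commonly round to 9.81).
#'
#' @param mass_g Mass in grams (>= 0).
#' @param g_m_per_s2 Gravitational acceleration; default standard gravity.
#' @return Force in uN.
#' @examples
#' weight_to_force(10, g_m_per_s2 = 9.81) / 1000  # 98.1 mN
#' @export
weight_to_force <- function(mass_g, g_m_per_s2 = 9.80665) {
  if (any(mass_g < 0)) {
    stop_microext("`mass_g` must be >= 0.", "microext_invalid_mass")
  }
  mass_g * g_m_per_s2 * 1000  # g * m/s^2 = mN -> uN
}

#' Zero the load cell (Set Offset)
#'
#' Averages `n_samples` bridge readings with no load on the cell and
#' records the mean as the offset; subsequent force conversions subtract
#' it, so the monitored force at zero load reads ~0. The no-load
#' precondition is a contract with the operator and cannot be verified in
#' software.
#'
#' @param cell A [load_cell_spec()].
#' @param n_samples Readings to average (default 100).
#' @param seed Optional RNG seed.
#' @return Offset estimate in bridge units.
#' @export
set_offset <- function(cell, n_samples = 100, seed = NULL) {
  if (n_samples < 1) {
    stop_microext("`n_samples` must be >= 1.", "microext_invalid_samples")
  }
  rb <- read_bridge(cell, force_uN = 0, n_samples = n_samples, seed = seed)
  if (rb$saturated) {
    stop_microext("saturated readings during Set Offset; calibration aborted.",
                  "microext_saturated")
  }
  rb$reading_units
}

#' Estimate the sensor gain from a reference weight (Calibrate Force)
#'
#' With the reference weight loaded (target force from
#' [weight_to_force()]), the gain is
#' `target_force / (mean_reading - offset)`; converting subsequent
#' readings with `(reading - offset) * gain` then reproduces the true
#' force. Single-point calibration, as in the documented workflow.
#'
#' @param cell A [load_cell_spec()].
#' @param offset_units Offset from [set_offset()].
#' @param target_force_uN Reference force in uN (> 0).
#' @param n_samples Readings to average.
#' @param seed Optional RNG seed.
#' @param applied_force_uN Force actually loading the cell; defaults to
#'   the target (weight in place). A mismatch simulates operator error
#'   (for example a forgotten weight, which yields the non-positive
#'   signal error).
#' @return An object of class `calibration_result` with fields
#'   `offset_units`, `gain_uN_per_unit`, `reference_force_uN`,
#'   `n_samples`, `residual_sd_units`, `timestamp`.
#' @export
calibrate_gain <- function(cell, offset_units, target_force_uN,
                           n_samples = 100, seed = NULL,
                           applied_force_uN = target_force_uN) {
  if (!is.finite(target_force_uN) || target_force_uN <= 0) {
    stop_microext("`target_force_uN` must be > 0.", "microext_invalid_target")
  }
  if (n_samples < 1) {
    stop_microext("`n_samples` must be >= 1.", "microext_invalid_samples")
  }
  rb <- read_bridge(cell, force_uN = applied_force_uN,
                    n_samples = n_samples, seed = seed)
  if (rb$saturated) {
    stop_microext("saturated readings during Calibrate Force; use a lighter weight or larger cell.",
                  "microext_saturated")
  }
  signal <- rb$reading_units - offset_units
  if (signal <= 0) {
    stop_microext("mean reading does not exceed the offset: missing weight or damaged cell?",
                  "microext_nonpositive_signal")
  }
  structure(
    list(offset_units = offset_units,
         gain_uN_per_unit = target_force_uN / signal,
         reference_force_uN = target_force_uN,
         n_samples = n_samples,
         residual_sd_units = rb$sd_units,
         timestamp = Sys.time()),
    class = "calibration_result"
  )
}

#' Compare two calibrations of the same sensor
#'
#' A large gain change between calibrations can indicate sensor damage.
#'
#' @param previous,current `calibration_result` objects.
#' @param tolerance_frac Relative gain-change threshold (default 10%).
#' @return `"pass"` or `"warn"`.
#' @export
validate_calibration <- function(previous, current, tolerance_frac = 0.1) {
  stopifnot(inherits(previous, "calibration_result"),
            inherits(current, "calibration_result"))
  rel <- abs(current$gain_uN_per_unit - previous$gain_uN_per_unit) /
    previous$gain_uN_per_unit
  if (rel > tolerance_frac) "warn" else "pass"
}

#' Run the full calibration workflow on an instrument
#'
#' Mirrors the documented procedure: orient the cell vertically, Set
#' Offset with no load, Calibrate Force against the reference weight,
#' return the cell to the horizontal working orientation (its self-weight
#' shifts the zero) and re-run Set Offset there. The instrument comes back
#' calibrated for horizontal operation with the monitored force at zero
#' load reading ~0.
#'
#' @param inst A [virtual_instrument()].
#' @param mass_g Reference weight in grams.
#' @param g_m_per_s2 Gravitational acceleration for [weight_to_force()].
#' @param n_samples Readings averaged per stage.
#' @param seed Optional RNG seed for the whole workflow.
#' @return The calibrated instrument; the `calibration` field holds the
#'   final `calibration_result`.
#' @export
calibrate_instrument <- function(inst, mass_g = 5, g_m_per_s2 = 9.80665,
                                 n_samples = 100, seed = NULL) {
  stopifnot(inherits(inst, "virtual_instrument"))
  run <- function() {
    cell_v <- inst$load_cell
    cell_v$orientation <- "vertical"
    offset_v <- set_offset(cell_v, n_samples = n_samples)
    target <- weight_to_force(mass_g, g_m_per_s2)
    cal <- calibrate_gain(cell_v, offset_v, target, n_samples = n_samples)
    # back to horizontal: self-weight shifts the zero; re-zero there
    cell_h <- inst$load_cell
    cell_h$orientation <- "horizontal"
    cal$offset_units <- set_offset(cell_h, n_samples = n_samples)
    cal
  }
  cal <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  inst$load_cell$orientation <- "horizontal"
  inst$calibration <- cal
  inst
}

#' Append a calibration to a CSV log
#'
#' Persists timestamped results so successive calibrations of the same
#' sensor can be compared with [validate_calibration()].
#'
#' @param cal A `calibration_result`.
#' @param path CSV file; created with a header when absent.
#' @return The log as a tibble, invisibly.
#' @export
write_calibration_log <- function(cal, path) {
  row <- tibble(
    timestamp = format(cal$timestamp, "%Y-%m-%dT%H:%M:%S"),
    offset_units = cal$offset_units,
    gain_uN_per_unit = cal$gain_uN_per_unit,
    reference_force_uN = cal$reference_force_uN,
    n_samples = cal$n_samples,
    residual_sd_units = cal$residual_sd_units
  )
  readr::write_csv(row, path, append = file.exists(path))
  invisible(readr::read_csv(path, show_col_types = FALSE))
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> offset = %.4f units, gain = %.2f uN/unit (ref %.0f uN, n = %d)\n",
    x$offset_units, x$gain_uN_per_unit, x$reference_force_uN, x$n_samples))
  invisible(x)
}
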