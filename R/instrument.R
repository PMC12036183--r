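#' Stepper-screw actuator specification
#'
#' A lead-screw linear actuator driven by a stepper motor. With the
#' defaults (1 mm pitch, 200 full steps per revolution, i.e. 1.8 deg per
#' step, no microstepping) one step moves the stage 5 um. The controller
#' can subdivide full steps via `microstep_divisor`.
#'
#' @param pitch_um_per_rev Screw pitch in um per revolution.
#' @param full_steps_per_rev Full motor steps per revolution.
#' @param microstep_divisor Microstepping divisor (>= 1).
#' @param travel_limit_um Maximum stage travel in um.
#' @param backlash_um Optional backlash (not modelled by default).
#' @return An object of class `actuator_spec`.
#' @examples
#' step_size_um(actuator_spec())  # 5 um
#' @export
actuator_spec <- function(pitch_um_per_rev = 1000,
                          full_steps_per_rev = 200,
                          microstep_divisor = 1,
                          travel_limit_um = 25000,
                          backlash_um = 0) {
  if (pitch_um_per_rev <= 0 || full_steps_per_rev <= 0 ||
      microstep_divisor < 1 || travel_limit_um <= 0 || backlash_um < 0) {
    stop_microext("invalid actuator specification (non-positive pitch, steps, travel, or divisor < 1).",
                  "microext_invalid_spec")
  }
  structure(
    list(pitch_um_per_rev = pitch_um_per_rev,
         full_steps_per_rev = full_steps_per_rev,
         microstep_divisor = microstep_divisor,
         travel_limit_um = travel_limit_um,
         backlash_um = backlash_um),
    class = "actuator_spec"
  )
}

#' Actuator step size
#'
#' `pitch / (full_steps_per_rev * microstep_divisor)`; 5 um with the
#' defaults.
#'
#' @param spec An [actuator_spec()].
#' @return Step size in um.
#' @export
step_size_um <- function(spec) {
  stopifnot(inherits(spec, "actuator_spec"))
  spec$pitch_um_per_rev / (spec$full_steps_per_rev * spec$microstep_divisor)
}

#' Load-cell specification
#'
#' A parallel-beam strain-gauge cell read through a Wheatstone bridge and
#' amplifier; the bridge reading is `F / true_gain + true_offset + noise`.
#' The true gain and offset are hidden from calibration code, which must
#' recover them via [set_offset()] and [calibrate_gain()]. The default
#' noise (0.01 units at 1000 uN/unit) gives ~10 uN RMS force noise, the
#' resolution of the 10 g cell; `capacity_uN` defaults to 10 g.
#'
#' @param true_gain_uN_per_unit True gain (uN per bridge unit).
#' @param true_offset_units True zero-load bridge offset.
#' @param noise_sd_units Gaussian read-noise sd, bridge units.
#' @param capacity_uN Saturation capacity in uN (10 g ~ 98066 uN).
#' @param orientation `"vertical"` (calibration rig) or `"horizontal"`
#'   (mounted); re-orienting shifts the zero-load offset by
#'   `orientation_shift_units` (sensor self-weight), which the calibration
#'   workflow must cancel by re-zeroing.
#' @param orientation_shift_units Offset shift when horizontal.
#' @return An object of class `load_cell_spec`.
#' @export
load_cell_spec <- function(true_gain_uN_per_unit = 1000,
                           true_offset_units = 0.2,
                           noise_sd_units = 0.01,
                           capacity_uN = 98066.5,
                           orientation = c("vertical", "horizontal"),
                           orientation_shift_units = 0) {
  orientation <- match.arg(orientation)
  if (true_gain_uN_per_unit <= 0 || noise_sd_units < 0 || capacity_uN <= 0) {
    stop_microext("gain and capacity must be > 0; noise sd >= 0.",
                  "microext_invalid_spec")
  }
  structure(
    list(true_gain_uN_per_unit = true_gain_uN_per_unit,
         true_offset_units = true_offset_units,
         noise_sd_units = noise_sd_units,
         capacity_uN = capacity_uN,
         orientation = orientation,
         orientation_shift_units = orientation_shift_units),
    class = "load_cell_spec"
  )
}

# effective zero-load offset for the cell's current orientation
.cell_offset <- function(cell) {
  cell$true_offset_units +
    if (cell$orientation == "horizontal") cell$orientation_shift_units else 0
}

#' Read the bridge at a known applied force
#'
#' Low-level sensor model used by the virtual instrument and by the
#' calibration rig (where a reference weight, not the specimen, loads the
#' cell). Returns the mean of `n_samples` noisy readings; forces beyond
#' capacity clip the reading at capacity and set the `saturated` flag
#' (real amplifiers clip rather than fail).
#'
#' @param cell A [load_cell_spec()].
#' @param force_uN True force applied to the cell.
#' @param n_samples Number of samples averaged (>= 1).
#' @param seed Optional seed for reproducible noise; when `NULL` the
#'   current RNG stream is used (experiments seed it once at start).
#' @return A list with `reading_units` (mean), `sd_units`, `saturated`.
#' @export
read_bridge <- function(cell, force_uN, n_samples = 1, seed = NULL) {
  stopifnot(inherits(cell, "load_cell_spec"))
  if (n_samples < 1) {
    stop_microext("`n_samples` must be >= 1.", "microext_invalid_samples")
  }
  saturated <- abs(force_uN) > cell$capacity_uN
  f_eff <- max(min(force_uN, cell$capacity_uN), -cell$capacity_uN)
  draw <- function() {
    noise <- if (cell$noise_sd_units > 0) {
      rnorm(n_samples, 0, cell$noise_sd_units)
    } else {
      rep(0, n_samples)
    }
    f_eff / cell$true_gain_uN_per_unit + .cell_offset(cell) + noise
  }
  samples <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(reading_units = mean(samples),
       sd_units = if (n_samples > 1) sd(samples) else cell$noise_sd_units,
       saturated = saturated,
       samples = samples)
}

#' Synthetic camera configuration
#'
#' Defines the field of view (in lab um) and pixel scale of the virtual
#' camera. Frames are 8-bit grayscale, dark-on-bright (India-ink dots on a
#' pale specimen); set `invert = TRUE` for the opposite polarity. The lab
#' x axis runs along the stretch direction with the fixed (sensor-side)
#' grip edge at 0.
#'
#' @param width_px,height_px Frame size in pixels.
#' @param scale_um_per_px Pixel scale (um per pixel).
#' @param origin_um Lab x of the left frame edge.
#' @param noise_sd Gaussian pixel noise sd (8-bit units).
#' @param invert Render bright-on-dark instead.
#' @param tag_width_um Rendered grip-tag width.
#' @param landmark_radius_um Rendered landmark dot radius.
#' @return An object of class `camera_config`.
#' @export
camera_config <- function(width_px = 760, height_px = 80,
                          scale_um_per_px = 10, origin_um = -600,
                          noise_sd = 0, invert = FALSE,
                          tag_width_um = 300, landmark_radius_um = 30) {
  if (width_px <= 0 || height_px <= 0 || scale_um_per_px <= 0) {
    stop_microext("camera dimensions and scale must be > 0.",
                  "microext_invalid_spec")
  }
  structure(
    list(width_px = as.integer(width_px), height_px = as.integer(height_px),
         scale_um_per_px = scale_um_per_px, origin_um = origin_um,
         noise_sd = noise_sd, invert = invert,
         tag_width_um = tag_width_um,
         landmark_radius_um = landmark_radius_um),
    class = "camera_config"
  )
}

#' Render a synthetic snapshot of the mounted specimen
#'
#' Draws a bright background, two dark grip tags whose separation tracks
#' the grip displacement, and anti-aliased dark circular landmarks at
#' [landmark_positions()] (so landmark separation tracks true tissue
#' strain, excluding slip). Deterministic given the RNG state when pixel
#' noise is enabled.
#'
#' @inheritParams specimen_force
#' @param landmark_fracs Material fractions of the landmark dots.
#' @param camera A [camera_config()].
#' @param timestamp_us Timestamp recorded in the frame metadata.
#' @return An object of class `extensometer_frame`: a list with `pixels`
#'   (numeric matrix, rows = y, 0--255), the camera metadata, and any
#'   field-of-view warnings.
#' @export
render_frame <- function(state, geom, landmark_fracs, camera,
                         timestamp_us = 0) {
  stopifnot(inherits(camera, "camera_config"))
  bg <- 230; tag_fg <- 40; dot_fg <- 25
  w <- camera$width_px; h <- camera$height_px; sc <- camera$scale_um_per_px

  # pixel j (1-based) has its centre at origin + (j - 0.5) * scale;
  # in "pixel coordinates" the centre of pixel j is j
  px_centers_um <- camera$origin_um + (seq_len(w) - 0.5) * sc

  img <- matrix(bg, nrow = h, ncol = w)

  # grip tags: fixed tag left of x = 0, moving tag right of the grip edge
  right_edge <- grip_separation(state, geom)
  tag_cols <- function(lo_um, hi_um) {
    # fractional horizontal coverage of [lo, hi] per pixel column
    lo_px <- (lo_um - camera$origin_um) / sc
    hi_px <- (hi_um - camera$origin_um) / sc
    cov <- pmin(hi_px, seq_len(w)) - pmax(lo_px, seq_len(w) - 1)
    pmin(pmax(cov, 0), 1)
  }
  for (tag in list(c(-camera$tag_width_um, 0),
                   c(right_edge, right_edge + camera$tag_width_um))) {
    cov <- tag_cols(tag[1], tag[2])
    hit <- which(cov > 0)
    if (length(hit)) {
      img[, hit] <- img[, hit] -
        matrix((bg - tag_fg) * cov[hit], nrow = h, ncol = length(hit),
               byrow = TRUE)
    }
  }

  warnings <- character()
  pos_um <- landmark_positions(state, geom, landmark_fracs)
  r_px <- camera$landmark_radius_um / sc
  y_c <- (h + 1) / 2
  for (p in pos_um) {
    x_c <- (p - camera$origin_um) / sc + 0.5  # pixel coordinate of centre
    if (x_c < 1 - r_px || x_c > w + r_px) {
      warnings <- c(warnings,
                    sprintf("landmark at %.1f um outside field of view", p))
      next
    }
    jlo <- max(1L, floor(x_c - r_px - 1)); jhi <- min(w, ceiling(x_c + r_px + 1))
    ilo <- max(1L, floor(y_c - r_px - 1)); ihi <- min(h, ceiling(y_c + r_px + 1))
    js <- jlo:jhi; is <- ilo:ihi
    d <- sqrt(outer((is - y_c)^2, (js - x_c)^2, "+"))
    cov <- pmin(pmax(r_px + 0.5 - d, 0), 1)  # anti-aliased disk coverage
    img[is, js] <- img[is, js] - (img[is, js] - dot_fg) * cov
  }

  if (camera$noise_sd > 0) {
    img <- img + matrix(rnorm(h * w, 0, camera$noise_sd), nrow = h)
  }
  img <- pmin(pmax(img, 0), 255)
  if (camera$invert) img <- 255 - img

  structure(
    list(pixels = img, width_px = w, height_px = h,
         scale_um_per_px = sc, origin_um = camera$origin_um,
         timestamp_us = timestamp_us, warnings = warnings),
    class = "extensometer_frame"
  )
}

#' Assemble a virtual instrument
#'
#' Bundles the actuator, load cell, camera and the mounted virtual
#' specimen into one functional object. All positions are kept internally
#' in nanometres; the actuator position is always an exact integer
#' multiple of the step size. Updates are functional: operations return a
#' new instrument.
#'
#' @param actuator An [actuator_spec()].
#' @param load_cell A [load_cell_spec()].
#' @param camera A [camera_config()] or `NULL` (no camera).
#' @param geom,params,state Specimen description and initial state.
#' @return An object of class `virtual_instrument`.
#' @export
virtual_instrument <- function(actuator = actuator_spec(),
                               load_cell = load_cell_spec(),
                               camera = camera_config(),
                               geom = specimen_geometry("cylindrical",
                                                        gauge_length_um = 5000,
                                                        radius_um = 100),
                               params = mechanical_params(),
                               state = specimen_state()) {
  structure(
    list(actuator = actuator, load_cell = load_cell, camera = camera,
         geom = geom, params = params, state = state,
         steps_taken = 0L, position_nm = 0, time_us = 0,
         calibration = NULL),
    class = "virtual_instrument"
  )
}

#' Move the actuator by whole steps
#'
#' Advances the stage by `n_steps` motor (micro)steps, updating the
#' position (exact multiple of the step size, logged in nm) and imposing
#' the new grip displacement on the specimen through [evolve_specimen()].
#' A request that would exceed the travel limit raises a range error and
#' performs no motion.
#'
#' @param inst A [virtual_instrument()].
#' @param n_steps Integer number of steps (may be negative).
#' @param dt_s Time the move-and-settle takes (s); the specimen evolves
#'   over this interval.
#' @return The updated instrument.
#' @export
move_steps <- function(inst, n_steps, dt_s = 1e-3) {
  stopifnot(inherits(inst, "virtual_instrument"))
  n_steps <- as.integer(n_steps)
  new_steps <- inst$steps_taken + n_steps
  step_um <- step_size_um(inst$actuator)
  new_pos_um <- new_steps * step_um
  if (new_pos_um < 0 || new_pos_um > inst$actuator$travel_limit_um) {
    stop_microext(
      sprintf("move to %.1f um exceeds travel limits [0, %g]; no motion performed.",
              new_pos_um, inst$actuator$travel_limit_um),
      "microext_travel_limit")
  }
  inst$steps_taken <- new_steps
  inst$position_nm <- new_steps * step_um * 1000
  inst$state <- evolve_specimen(inst$state, inst$geom, inst$params,
                                x_grip_target_um = new_pos_um, dt_s = dt_s)
  inst$time_us <- inst$time_us + dt_s * 1e6
  inst
}

#' Let the instrument dwell (specimen relaxes / creeps)
#'
#' @param inst A [virtual_instrument()].
#' @param dt_s Dwell time in seconds.
#' @return The updated instrument.
#' @export
dwell <- function(inst, dt_s) {
  inst$state <- evolve_specimen(inst$state, inst$geom, inst$params,
                                x_grip_target_um = inst$position_nm / 1000,
                                dt_s = dt_s)
  inst$time_us <- inst$time_us + dt_s * 1e6
  inst
}

#' Measure the force currently transmitted to the load cell
#'
#' Reads the bridge (averaging `n_samples` draws) at the specimen's
#' current true force and converts to uN with the instrument's
#' calibration. Errors if the instrument has not been calibrated.
#'
#' @param inst A [virtual_instrument()].
#' @param n_samples Samples to average.
#' @return A list with `force_uN`, `reading_units`, `saturated`.
#' @export
measure_force <- function(inst, n_samples = 25) {
  if (is.null(inst$calibration)) {
    stop_microext("instrument is not calibrated; run the calibration workflow first.",
                  "microext_not_calibrated")
  }
  f_true <- specimen_force(inst$state, inst$geom, inst$params)
  rb <- read_bridge(inst$load_cell, f_true, n_samples = n_samples)
  list(force_uN = (rb$reading_units - inst$calibration$offset_units) *
         inst$calibration$gain_uN_per_unit,
       reading_units = rb$reading_units,
       saturated = rb$saturated,
       samples = rb$samples)
}

#' Snapshot the mounted specimen
#'
#' @param inst A [virtual_instrument()].
#' @param landmark_fracs Material fractions of the landmark dots.
#' @return An `extensometer_frame` (or `NULL` when no camera is fitted).
#' @export
capture_snapshot <- function(inst, landmark_fracs = c(0.2, 0.8)) {
  if (is.null(inst$camera)) return(NULL)
  render_frame(inst$state, inst$geom, landmark_fracs, inst$camera,
               timestamp_us = inst$time_us)
}

#' @export
print.virtual_instrument <- function(x, ...) {
  cat(sprintf("<virtual_instrument> pos = %g nm (%d steps), t = %.2f s, %s\n",
              x$position_nm, x$steps_taken, x$time_us / 1e6,
              if (is.null(x$calibration)) "uncalibrated" else "calibrated"))
  invisible(x)
}
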