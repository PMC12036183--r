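#' Experiment configuration
#'
#' Parameters of an automated stretching run, mirroring the instrument's
#' workflow parameters: total Distance, Step Size, Wait Time (the
#' force-stabilization dwell between steps; `-1` requests external-trigger
#' mode, where the run blocks at each step until a confirmation callback
#' fires), and Creep Threshold (`0` = plain ramp, the default; `> 0`
#' switches to constant-force creep control).
#'
#' @param mode `"ramp"` or `"creep"`.
#' @param distance_um Total stretch distance in um (> 0).
#' @param step_size_um Commanded step size in um; must be an integer
#'   multiple of the actuator (micro)step.
#' @param wait_time_s Dwell after each step, seconds; `-1` = external
#'   trigger; `0` = no stabilization wait.
#' @param creep_threshold_uN Force threshold for creep mode (uN); 0
#'   disables creep control.
#' @param approach_rate_um_per_s Creep phase-1 stretch rate (default one
#'   5-um step per second).
#' @param max_duration_s Creep phase-2 hold duration.
#' @param deadband_frac Creep control deadband as a fraction of the
#'   threshold (default 1%).
#' @param control_period_s Creep control-loop period (s).
#' @param n_force_samples Bridge samples averaged per force reading.
#' @param landmark_fracs Material fractions of the rendered landmarks.
#' @param capture_frames Capture a snapshot per step?
#' @param snapshot_every Capture a snapshot every this many records
#'   (default 1, i.e. one snapshot per step; creep holds often use a
#'   sparser cadence to keep long runs light).
#' @param seed Single RNG seed for the whole experiment.
#' @param trigger Callback `function(step)` for external-trigger mode;
#'   default auto-confirms.
#' @param stop_after Optional early stop: a step index, or a predicate
#'   `function(step, force_uN)` returning `TRUE` to stop after the
#'   current step (the "Stop" button). A stopped run keeps its partial
#'   log and does not auto-return the actuator.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(mode = c("ramp", "creep"),
                              distance_um,
                              step_size_um = 5,
                              wait_time_s = 1,
                              creep_threshold_uN = 0,
                              approach_rate_um_per_s = 5,
                              max_duration_s = 600,
                              deadband_frac = 0.01,
                              control_period_s = 1,
                              n_force_samples = 25,
                              landmark_fracs = c(0.2, 0.8),
                              capture_frames = TRUE,
                              snapshot_every = 1L,
                              seed = 1,
                              trigger = NULL,
                              stop_after = NULL) {
  mode <- match.arg(mode)
  if (!is.numeric(distance_um) || distance_um <= 0 || step_size_um <= 0) {
    stop_microext("`distance_um` and `step_size_um` must be > 0.",
                  "microext_invalid_config")
  }
  if (creep_threshold_uN < 0) {
    stop_microext("`creep_threshold_uN` must be >= 0.",
                  "microext_invalid_config")
  }
  if (!(wait_time_s >= 0 || wait_time_s == -1)) {
    stop_microext("`wait_time_s` must be >= 0, or -1 for external-trigger mode.",
                  "microext_invalid_config")
  }
  structure(
    list(mode = mode, distance_um = distance_um, step_size_um = step_size_um,
         wait_time_s = wait_time_s, creep_threshold_uN = creep_threshold_uN,
         approach_rate_um_per_s = approach_rate_um_per_s,
         max_duration_s = max_duration_s, deadband_frac = deadband_frac,
         control_period_s = control_period_s,
         n_force_samples = n_force_samples,
         landmark_fracs = landmark_fracs, capture_frames = capture_frames,
         snapshot_every = as.integer(snapshot_every),
         seed = seed, trigger = trigger, stop_after = stop_after),
    class = "experiment_config"
  )
}

# settle time used when there is no stabilization wait (wait_time 0 or -1)
.SETTLE_S <- 0.05
# time a single move takes in the simulation clock
.MOVE_S <- 0.01

# one move + dwell + reading (+ snapshot); shared by ramp, creep and
# manual stretching so their logs are step-for-step comparable
.do_step <- function(inst, micro_steps, dwell_s, config,
                     capture = isTRUE(config$capture_frames)) {
  if (micro_steps != 0) inst <- move_steps(inst, micro_steps, dt_s = .MOVE_S)
  inst <- dwell(inst, max(dwell_s, .SETTLE_S))
  m <- measure_force(inst, n_samples = config$n_force_samples)
  frame <- if (capture) {
    capture_snapshot(inst, config$landmark_fracs)
  }
  list(inst = inst, force_uN = m$force_uN, saturated = m$saturated,
       samples = m$samples, frame = frame)
}

.raw_rows <- function(inst, samples) {
  n <- length(samples)
  tibble(time_us = inst$time_us - rev(seq_len(n) - 1) * 1e3,
         raw_reading_units = samples,
         position_nm = inst$position_nm)
}

.should_stop <- function(config, step, force) {
  sa <- config$stop_after
  if (is.null(sa)) return(FALSE)
  if (is.function(sa)) isTRUE(sa(step, force)) else step >= sa
}

.new_log <- function(config, records, raw, frames, status, inst, started) {
  structure(
    list(config = config,
         records = dplyr::bind_rows(records),
         raw = dplyr::bind_rows(raw),
         frames = frames, status = status, instrument = inst,
         started = started),
    class = "experiment_log"
  )
}

#' Run an automated ramp (stretch-to-distance) experiment
#'
#' Loops move-one-step, wait for stabilization, read force, capture a
#' snapshot, append a record, until the total distance is covered or the
#' run is stopped/saturated. On completion the actuator automatically
#' returns to its starting position (a stopped run does not). A rupture
#' mid-run is recorded in the log (forces drop to ~0) and flagged in the
#' end status; the run itself continues to the configured distance.
#'
#' @param config An [experiment_config()].
#' @param inst A calibrated [virtual_instrument()].
#' @return An `experiment_log`: config, a `records` tibble (step,
#'   position_nm, force_uN, time_us, snapshot), the raw sensor stream,
#'   captured frames, end status (`completed`, `ruptured`, `stopped`),
#'   and the final instrument.
#' @export
run_ramp <- function(config, inst) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(inst, "virtual_instrument"))
  act_step <- step_size_um(inst$actuator)
  micro <- config$step_size_um / act_step
  if (abs(micro - round(micro)) > 1e-9) {
    stop_microext("`step_size_um` must be an integer multiple of the actuator step.",
                  "microext_invalid_config")
  }
  micro <- as.integer(round(micro))
  n_steps <- as.integer(ceiling(config$distance_um / config$step_size_um))
  end_um <- inst$position_nm / 1000 + n_steps * config$step_size_um
  if (end_um > inst$actuator$travel_limit_um) {
    stop_microext("configured distance exceeds the actuator travel limit.",
                  "microext_travel_limit")
  }
  started <- Sys.time()
  trigger <- config$trigger %||% function(step) TRUE

  withr::with_seed(config$seed, {
    records <- vector("list", n_steps)
    raw <- vector("list", n_steps)
    frames <- list()
    status <- "completed"
    taken <- 0L
    for (k in seq_len(n_steps)) {
      if (config$wait_time_s == -1) trigger(k)
      dwell_s <- if (config$wait_time_s > 0) config$wait_time_s else 0
      st <- .do_step(inst, micro, dwell_s, config,
                     capture = isTRUE(config$capture_frames) &&
                       k %% config$snapshot_every == 0L)
      inst <- st$inst
      snap <- if (is.null(st$frame)) NA_character_ else
        sprintf("snapshot-%04d.png", k)
      records[[k]] <- tibble(step = k, position_nm = inst$position_nm,
                             force_uN = st$force_uN, time_us = inst$time_us,
                             snapshot = snap)
      raw[[k]] <- .raw_rows(inst, st$samples)
      if (!is.null(st$frame)) frames[[length(frames) + 1L]] <- st$frame
      taken <- k
      if (st$saturated) { status <- "stopped"; break }
      if (.should_stop(config, k, st$force_uN)) { status <- "stopped"; break }
    }
    if (status == "completed") {
      if (inst$state$ruptured) status <- "ruptured"
      inst <- move_steps(inst, -taken * micro, dt_s = .MOVE_S)  # auto-return
    }
    .new_log(config, records[seq_len(taken)], raw[seq_len(taken)],
             frames, status, inst, started)
  })
}

#' Run a constant-force creep experiment
#'
#' Phase 1 stretches at `approach_rate_um_per_s` (one step per period)
#' until the measured force reaches `creep_threshold_uN`; phase 2 then
#' holds the force for `max_duration_s`: each control period the specimen
#' relaxes/creeps, the force is read, and when it falls below
#' `threshold * (1 - deadband_frac)` single steps are issued until it is
#' back within the band. One record is logged per control tick whether or
#' not a step was issued. A threshold of 0 delegates to [run_ramp()]
#' (elasticity experiments); a threshold above the sensor capacity is a
#' configuration error.
#'
#' @inheritParams run_ramp
#' @return An `experiment_log` (see [run_ramp()]); records gain a
#'   `phase` column (`"approach"` or `"hold"`).
#' @export
run_creep <- function(config, inst) {
  stopifnot(inherits(config, "experiment_config"),
            inherits(inst, "virtual_instrument"))
  thr <- config$creep_threshold_uN
  if (thr == 0) return(run_ramp(config, inst))
  if (thr > inst$load_cell$capacity_uN) {
    stop_microext("`creep_threshold_uN` exceeds the load-cell capacity.",
                  "microext_invalid_config")
  }
  act_step <- step_size_um(inst$actuator)
  micro <- as.integer(round(config$step_size_um / act_step))
  approach_period <- config$step_size_um / config$approach_rate_um_per_s
  started <- Sys.time()

  withr::with_seed(config$seed, {
    records <- list(); raw <- list(); frames <- list()
    status <- "completed"
    k <- 0L
    repeat {  # phase 1: approach at constant rate
      k <- k + 1L
      st <- .do_step(inst, micro,
                     approach_period - .MOVE_S - .SETTLE_S, config,
                     capture = isTRUE(config$capture_frames) &&
                       k %% config$snapshot_every == 0L)
      inst <- st$inst
      records[[k]] <- tibble(step = k, position_nm = inst$position_nm,
                             force_uN = st$force_uN, time_us = inst$time_us,
                             snapshot = if (is.null(st$frame)) NA_character_
                                        else sprintf("snapshot-%04d.png", k),
                             phase = "approach")
      raw[[k]] <- .raw_rows(inst, st$samples)
      if (!is.null(st$frame)) frames[[length(frames) + 1L]] <- st$frame
      if (st$saturated) { status <- "stopped"; break }
      if (st$force_uN >= thr) break
      if (inst$position_nm / 1000 + config$step_size_um >
          inst$actuator$travel_limit_um) { status <- "stopped"; break }
      if (inst$time_us / 1e6 > config$max_duration_s) {
        status <- "timed_out"; break
      }
    }

    if (status == "completed") {
      t_hold_start <- inst$time_us / 1e6
      lower <- thr * (1 - config$deadband_frac)
      while (inst$time_us / 1e6 - t_hold_start < config$max_duration_s) {
        k <- k + 1L
        st <- .do_step(inst, 0L, config$control_period_s - .SETTLE_S, config,
                       capture = FALSE)
        inst <- st$inst
        force <- st$force_uN
        samples <- st$samples
        n_corr <- 0L
        while (force < lower && n_corr < 50L) {
          # issue single steps until back within the band
          cr <- .do_step(inst, micro, 0, config)
          inst <- cr$inst
          force <- cr$force_uN
          samples <- c(samples, cr$samples)
          n_corr <- n_corr + 1L
          if (inst$position_nm / 1000 + config$step_size_um >
              inst$actuator$travel_limit_um) break
        }
        frame <- if (isTRUE(config$capture_frames) &&
                     k %% config$snapshot_every == 0L) {
          capture_snapshot(inst, config$landmark_fracs)
        }
        if (!is.null(frame)) frames[[length(frames) + 1L]] <- frame
        records[[k]] <- tibble(step = k, position_nm = inst$position_nm,
                               force_uN = force, time_us = inst$time_us,
                               snapshot = if (is.null(frame)) NA_character_
                                          else sprintf("snapshot-%04d.png", k),
                               phase = "hold")
        raw[[k]] <- .raw_rows(inst, samples)
        if (st$saturated) { status <- "stopped"; break }
        if (.should_stop(config, k, force)) { status <- "stopped"; break }
        if (inst$state$ruptured) { status <- "ruptured"; break }
      }
    }
    .new_log(config, records, raw, frames, status, inst, started)
  })
}

#' Single manual stretching step
#'
#' Moves the actuator by `distance_um`, waits for stabilization, reads
#' the force and optionally captures a snapshot; a sequence of manual
#' steps with the same schedule reproduces a [run_ramp()] log.
#'
#' @param inst A calibrated [virtual_instrument()].
#' @param distance_um Move distance ("Move Measure"); may be 0 to re-read.
#' @param wait_time_s Stabilization wait.
#' @param step Step index recorded in the returned row.
#' @param config Optional [experiment_config()] supplying sampling and
#'   camera settings; a default is built when omitted.
#' @return A list with `record` (one-row tibble), `frame`, and the
#'   updated `inst`.
#' @export
manual_step <- function(inst, distance_um, wait_time_s = 1, step = 1L,
                        config = NULL) {
  if (is.null(config)) {
    config <- experiment_config("ramp", distance_um = max(distance_um, 1),
                                wait_time_s = wait_time_s)
  }
  act_step <- step_size_um(inst$actuator)
  micro <- as.integer(round(distance_um / act_step))
  st <- .do_step(inst, micro, if (wait_time_s > 0) wait_time_s else 0, config)
  list(record = tibble(step = as.integer(step),
                       position_nm = st$inst$position_nm,
                       force_uN = st$force_uN, time_us = st$inst$time_us,
                       snapshot = NA_character_),
       frame = st$frame, inst = st$inst)
}

#' @export
print.experiment_log <- function(x, ...) {
  cat(sprintf("<experiment_log> %s mode, %d records, status: %s\n",
              x$config$mode, nrow(x$records), x$status))
  print(head(x$records))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
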