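#' Write an experiment run directory
#'
#' Writes the standard run artifacts: `Extensometer.csv` (one row per
#' step, header `Step,Position (nm),Force (µN),Time (µs)`, UTF-8 with the
#' micro signs preserved), `MRXlog.csv` (the raw sensor stream:
#' `time_us,raw_reading_units,position_nm`), a `Snapshots/` folder of PNG
#' frames (one per step with a snapshot), and a `config.yaml` snapshot
#' sufficient to reproduce the run. CSVs are written to a temporary file
#' and renamed, so no partial file is ever left behind.
#'
#' @param log An `experiment_log` from [run_ramp()] / [run_creep()].
#' @param dir Target directory; created if needed. By default a
#'   timestamped name (`run-YYYYMMDD-HHMMSS`) carrying the experiment
#'   start time is appended.
#' @param timestamped Append the timestamped subdirectory?
#' @return The run directory path, invisibly, with attribute `files`.
#' @export
write_run_dir <- function(log, dir, timestamped = FALSE) {
  stopifnot(inherits(log, "experiment_log"))
  if (timestamped) {
    dir <- file.path(dir, format(log$started, "run-%Y%m%d-%H%M%S"))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  ext <- log$records[, c("step", "position_nm", "force_uN", "time_us")]
  # full-precision decimal rendering so the CSV round-trips bit-for-bit
  ext[-1] <- lapply(ext[-1], function(x) sprintf("%.17g", x))
  names(ext) <- c("Step", "Position (nm)", "Force (µN)", "Time (µs)")
  write_atomic <- function(df, path) {
    tmp <- tempfile(tmpdir = dir, fileext = ".csv")
    readr::write_csv(df, tmp)
    file.rename(tmp, path)
  }
  write_atomic(ext, file.path(dir, "Extensometer.csv"))
  if (!is.null(log$raw) && nrow(log$raw) > 0) {
    write_atomic(log$raw, file.path(dir, "MRXlog.csv"))
  }

  snaps <- character()
  if (length(log$frames) > 0) {
    snap_dir <- file.path(dir, "Snapshots")
    dir.create(snap_dir, showWarnings = FALSE)
    names_used <- log$records$snapshot[!is.na(log$records$snapshot)]
    for (i in seq_along(log$frames)) {
      nm <- if (i <= length(names_used)) names_used[i] else
        sprintf("snapshot-%04d.png", i)
      png::writePNG(log$frames[[i]]$pixels / 255, file.path(snap_dir, nm))
      snaps <- c(snaps, nm)
    }
  }

  cfg <- log$config
  cfg$trigger <- NULL
  cfg$stop_after <- NULL
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))

  out <- structure(dir,
                   files = c("Extensometer.csv", "MRXlog.csv", "config.yaml",
                             snaps))
  invisible(out)
}

# canonical column names and their accepted header aliases
.ext_aliases <- list(
  step = c("Step", "step"),
  position_nm = c("Position (nm)", "position_nm"),
  force_uN = c("Force (µN)", "Force (uN)", "force_uN"),
  time_us = c("Time (µs)", "Time (us)", "time_us")
)

#' Read an Extensometer.csv log
#'
#' Tolerant to header variants with or without the micro sign
#' (`Force (µN)` / `Force (uN)`), strict on column count and row shape:
#' a missing required column or a truncated row raises a schema error
#' naming the column or row.
#'
#' @param path Path to the CSV file.
#' @return An `experiment_log` with the `records` tibble populated
#'   (snapshot paths are not stored in the CSV) and status `"completed"`.
#' @export
read_extensometer_log <- function(path) {
  if (!file.exists(path)) {
    stop_microext(sprintf("file not found: %s", path), "microext_io_error")
  }
  # read everything as text, convert with base R's correctly rounded
  # strtod so the full-precision round trip is exact
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()),
                         locale = readr::locale(encoding = "UTF-8"))
  nm <- names(raw)
  canon <- vapply(nm, function(x) {
    hit <- names(.ext_aliases)[vapply(.ext_aliases, function(a) x %in% a,
                                      logical(1))]
    if (length(hit) == 1) hit else NA_character_
  }, character(1))
  missing <- setdiff(names(.ext_aliases), canon[!is.na(canon)])
  if (length(missing) > 0) {
    stop_microext(sprintf("missing required column(s): %s",
                          paste(missing, collapse = ", ")),
                  "microext_schema_error")
  }
  if (ncol(raw) != length(.ext_aliases)) {
    stop_microext(sprintf("expected %d columns, found %d.",
                          length(.ext_aliases), ncol(raw)),
                  "microext_schema_error")
  }
  names(raw) <- canon
  raw <- as_tibble(raw)[, names(.ext_aliases)]
  raw[] <- suppressWarnings(lapply(raw, as.numeric))
  bad <- which(!stats::complete.cases(raw))
  if (length(bad) > 0) {
    stop_microext(sprintf("malformed/truncated data at row %d.", bad[1]),
                  "microext_schema_error")
  }
  records <- raw
  records$step <- as.integer(records$step)
  records$snapshot <- NA_character_
  structure(list(config = NULL, records = records, raw = NULL,
                 frames = list(), status = "completed", instrument = NULL,
                 started = NA),
            class = "experiment_log")
}

#' Read a snapshot folder
#'
#' Loads PNG frames (sorted by filename) as matrices of 8-bit
#' intensities, ready for [track_landmarks()].
#'
#' @param dir Snapshot directory.
#' @param scale_um_per_px Pixel scale to attach to each frame.
#' @return A list of `extensometer_frame` objects.
#' @export
read_snapshots <- function(dir, scale_um_per_px = NULL) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) {
    stop_microext(sprintf("no PNG snapshots found in %s", dir),
                  "microext_io_error")
  }
  lapply(seq_along(files), function(i) {
    px <- png::readPNG(files[[i]])
    if (length(dim(px)) == 3) px <- px[, , 1]
    structure(list(pixels = px * 255, width_px = ncol(px),
                   height_px = nrow(px), scale_um_per_px = scale_um_per_px,
                   origin_um = NA_real_, timestamp_us = as.numeric(i),
                   warnings = character()),
              class = "extensometer_frame")
  })
}

#' One-command simulated workflow (calibrate, stretch to break, track,
#' analyze)
#'
#' Builds the default virtual specimen and instrument, runs the full
#' calibration workflow against a 5 g reference weight, stretches the
#' specimen to rupture while capturing snapshots, tracks the landmark
#' dots, computes both strain pathways, and summarizes the mechanics.
#' Deterministic given `seed`.
#'
#' @param seed Single seed for all randomness.
#' @param dir Optional directory: when given, the run directory, track
#'   and strain CSVs and a `summary.json` are written there.
#' @param slip Enable grip slippage (the specimen then slides in its
#'   tags once the force exceeds the holding threshold, and the grip
#'   pathway overestimates strain).
#' @param E_inf_MPa Equilibrium modulus of the demo specimen.
#' @return A list: `log`, `track`, `series` (strain pathways), `curve`,
#'   `summary` (a `mechanical_summary`), `slippage` (diagnosis), `geom`,
#'   and `dir`.
#' @export
run_demo <- function(seed = 1, dir = NULL, slip = FALSE, E_inf_MPa = 20) {
  geom <- specimen_geometry("cylindrical", gauge_length_um = 5000,
                            radius_um = 100)
  params <- mechanical_params(E_inf_MPa = E_inf_MPa,
                              E_1_MPa = E_inf_MPa / 2)
  if (slip) {
    params$F_hold_uN <- 2000
    params$slip_rate_um_per_s_per_uN <- 5e-4
  }
  inst <- virtual_instrument(geom = geom, params = params)
  inst <- calibrate_instrument(inst, mass_g = 5, seed = seed)

  config <- experiment_config("ramp", distance_um = 1000, step_size_um = 5,
                              wait_time_s = 2, seed = seed + 1)
  log <- run_ramp(config, inst)

  track <- track_landmarks(log$frames)
  lmk <- landmark_strain(track)
  grp <- grip_strain(log, L0_um = geom$gauge_length_um)
  series <- strain_series(lmk, grp)
  curve <- stress_strain_curve(log$records$force_uN,
                               series$landmark_strain_pct, geom,
                               step = series$step)
  summary <- mechanical_summary(curve, log$records$force_uN, geom,
                                span_steps = 30)
  diagnosis <- slippage_diagnosis(series)

  if (!is.null(dir)) {
    run_dir <- write_run_dir(log, dir)
    readr::write_csv(track, file.path(dir, "track.csv"))
    readr::write_csv(diagnosis$per_step, file.path(dir, "strain.csv"))
    out <- as.list(glance(summary))
    out$slippage_verdict <- diagnosis$verdict
    out$status <- log$status
    jsonlite::write_json(out, file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(log = log, track = track, series = series, curve = curve,
       summary = summary, slippage = diagnosis, geom = geom,
       params = params, dir = dir)
}
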