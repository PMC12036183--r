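test_that("experiment configs enforce their invariants", {
  expect_error(experiment_config("ramp", distance_um = 0),
               class = "microext_invalid_config")
  expect_error(experiment_config("ramp", distance_um = 100,
                                 step_size_um = 0),
               class = "microext_invalid_config")
  expect_error(experiment_config("creep", distance_um = 100,
                                 creep_threshold_uN = -5),
               class = "microext_invalid_config")
  expect_error(experiment_config("ramp", distance_um = 100,
                                 wait_time_s = -2),
               class = "microext_invalid_config")
  cfg <- experiment_config("ramp", distance_um = 250, step_size_um = 5)
  expect_identical(ceiling(cfg$distance_um / cfg$step_size_um), 50)
})

test_that("a ramp over 250 um at 5 um/step logs 50 exact records and returns home", {
  inst <- calibrated_instrument(cell = quiet_cell())
  cfg <- experiment_config("ramp", distance_um = 250, step_size_um = 5,
                           wait_time_s = 0.2, capture_frames = FALSE,
                           seed = 2)
  log <- run_ramp(cfg, inst)
  expect_identical(nrow(log$records), 50L)
  expect_identical(log$status, "completed")
  # position of record k is exactly k * step_size (in nm)
  expect_identical(log$records$position_nm, as.numeric(1:50) * 5000)
  expect_true(all(diff(log$records$time_us) > 0))
  # snapshots disabled -> none recorded
  expect_true(all(is.na(log$records$snapshot)))
  # actuator auto-returned to start
  expect_identical(log$instrument$position_nm, 0)
})

test_that("step-force increments match the relaxed and unrelaxed stiffness limits", {
  geom <- default_geom()
  p <- mechanical_params(E_inf_MPa = 20, E_1_MPa = 10, tau_s = 5,
                         sigma_Y_MPa = 4.9, phi_per_MPa_s = 0,
                         sigma_ult_MPa = 5)
  A <- cross_section_area(geom)
  L0 <- geom$gauge_length_um

  run_with_wait <- function(wait_s, n = 15) {
    inst <- calibrated_instrument(geom = geom, params = p,
                                  cell = quiet_cell())
    cfg <- experiment_config("ramp", distance_um = n * 5, step_size_um = 5,
                             wait_time_s = wait_s, capture_frames = FALSE,
                             seed = 3)
    run_ramp(cfg, inst)$records$force_uN
  }

  # wait >> tau: relaxation completes, increment -> E_inf * A / L0 * step
  f_slow <- run_with_wait(10 * p$tau_s)
  expect_equal(mean(diff(f_slow)), 20 * A / L0 * 5, tolerance = 0.02)

  # wait << tau: no relaxation, increment -> (E_inf + E_1) * A / L0 * step
  f_fast <- run_with_wait(0, n = 6)
  expect_equal(mean(diff(f_fast)[1:3]), 30 * A / L0 * 5, tolerance = 0.02)
})

test_that("a weak specimen ruptures mid-run: force collapses, status flags it", {
  p <- mechanical_params(sigma_ult_MPa = 0.5, sigma_Y_MPa = 0.4,
                         phi_per_MPa_s = 0)
  inst <- calibrated_instrument(params = p, cell = quiet_cell())
  cfg <- experiment_config("ramp", distance_um = 500, step_size_um = 5,
                           wait_time_s = 0.2, capture_frames = FALSE,
                           seed = 4)
  log <- run_ramp(cfg, inst)
  expect_identical(log$status, "ruptured")
  f <- log$records$force_uN
  expect_gt(max(f), 0)
  drop_at <- detect_rupture(f)
  expect_false(is.na(drop_at))
  expect_true(all(f[drop_at:length(f)] == 0))
})

test_that("stop ends the run after the current step with a valid partial log", {
  inst <- calibrated_instrument(cell = quiet_cell())
  cfg <- experiment_config("ramp", distance_um = 250, step_size_um = 5,
                           wait_time_s = 0.2, capture_frames = FALSE,
                           stop_after = 10, seed = 5)
  log <- run_ramp(cfg, inst)
  expect_identical(log$status, "stopped")
  expect_identical(nrow(log$records), 10L)
  # stopped actuator is NOT auto-returned
  expect_identical(log$instrument$position_nm, 10 * 5000)

  # a stopped log round-trips through the same CSV format as a completed one
  dir <- withr::local_tempdir()
  write_run_dir(log, dir)
  back <- read_extensometer_log(file.path(dir, "Extensometer.csv"))
  expect_equal(back$records$position_nm, log$records$position_nm)
  expect_equal(back$records$force_uN, log$records$force_uN)

  # manual return-to-start restores position 0 exactly
  inst_back <- move_steps(log$instrument, -10)
  expect_identical(inst_back$position_nm, 0)
})

test_that("repeated manual steps reproduce the automated ramp log", {
  mk <- function() calibrated_instrument(cell = quiet_cell())
  cfg <- experiment_config("ramp", distance_um = 25, step_size_um = 5,
                           wait_time_s = 1, capture_frames = FALSE, seed = 6)
  auto <- run_ramp(cfg, mk())

  inst <- mk()
  rows <- list()
  for (k in 1:5) {
    ms <- manual_step(inst, 5, wait_time_s = 1, step = k, config = cfg)
    inst <- ms$inst
    rows[[k]] <- ms$record
  }
  manual <- dplyr::bind_rows(rows)
  expect_equal(manual$position_nm, auto$records$position_nm)
  expect_equal(manual$force_uN, auto$records$force_uN)
  expect_equal(manual$time_us, auto$records$time_us)

  # a 0-um manual step re-reads without moving
  ms0 <- manual_step(inst, 0, wait_time_s = 0.1, config = cfg)
  expect_identical(ms0$record$position_nm, inst$position_nm)
})

test_that("external-trigger mode blocks per step and reproduces the wait-0 log", {
  mk <- function() calibrated_instrument(cell = quiet_cell())
  base <- experiment_config("ramp", distance_um = 25, step_size_um = 5,
                            wait_time_s = 0, capture_frames = FALSE,
                            seed = 7)
  ref <- run_ramp(base, mk())

  fired <- integer()
  trig <- experiment_config("ramp", distance_um = 25, step_size_um = 5,
                            wait_time_s = -1, capture_frames = FALSE,
                            seed = 7,
                            trigger = function(k) fired <<- c(fired, k))
  log <- run_ramp(trig, mk())
  expect_identical(fired, 1:5)
  expect_equal(log$records$force_uN, ref$records$force_uN)
  expect_equal(log$records$position_nm, ref$records$position_nm)
})

test_that("creep control holds the threshold force without overshooting the band", {
  geom <- default_geom()
  p <- mechanical_params(sigma_Y_MPa = 0.05, phi_per_MPa_s = 5e-4,
                         sigma_ult_MPa = 2.5)
  inst <- calibrated_instrument(
    geom = geom, params = p,
    actuator = actuator_spec(microstep_divisor = 16))
  thr <- 5000
  cfg <- experiment_config("creep", distance_um = 5000,
                           step_size_um = 0.3125, creep_threshold_uN = thr,
                           approach_rate_um_per_s = 5, max_duration_s = 60,
                           capture_frames = FALSE, seed = 8)
  log <- run_creep(cfg, inst)
  hold <- log$records[log$records$phase == "hold", ]
  expect_gt(nrow(hold), 30)
  # never exceeds threshold + one-step increment + noise allowance
  step_inc <- (p$E_inf_MPa + p$E_1_MPa) *
    cross_section_area(geom) / geom$gauge_length_um * 0.3125
  noise_uN <- 4 * 1000 * 0.01 / sqrt(cfg$n_force_samples)
  expect_lt(max(hold$force_uN), thr + step_inc + noise_uN)
  # and stays at the threshold (within the deadband) almost always
  in_band <- abs(hold$force_uN - thr) <= cfg$deadband_frac * thr + noise_uN
  expect_gte(mean(in_band), 0.95)
})

test_that("creep with threshold 0 is an ordinary ramp; impossible thresholds error", {
  inst <- calibrated_instrument(cell = quiet_cell())
  cfg0 <- experiment_config("creep", distance_um = 25, step_size_um = 5,
                            wait_time_s = 0.2, creep_threshold_uN = 0,
                            capture_frames = FALSE, seed = 9)
  log <- run_creep(cfg0, inst)
  expect_identical(nrow(log$records), 5L)
  expect_false("phase" %in% names(log$records))

  cfg_bad <- experiment_config("creep", distance_um = 25, step_size_um = 5,
                               creep_threshold_uN = 1e9)
  expect_error(run_creep(cfg_bad, inst), class = "microext_invalid_config")
})
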