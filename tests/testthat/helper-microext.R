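# Shared fixtures and independent oracles, built in code.

default_geom <- function() {
  specimen_geometry("cylindrical", gauge_length_um = 5000, radius_um = 100)
}

quiet_cell <- function(...) {
  load_cell_spec(noise_sd_units = 0, ...)
}

# Independent fine-step explicit Euler integration of the constitutive
# laws (step-and-hold grip semantics), used as the reference the package
# integrator must reproduce. Deliberately naive: first-order, tiny steps.
euler_oracle <- function(state, geom, params, x_grip, dt, h = params$tau_s / 4000) {
  A <- cross_section_area(geom)
  L0 <- geom$gauge_length_um
  ev <- state$eps_v; ep <- state$eps_p; xs <- state$x_slip_um
  rupt <- state$ruptured
  n <- ceiling(dt / h); h <- dt / n
  for (i in seq_len(n)) {
    if (rupt) break
    et <- (x_grip - xs) / L0
    sig <- params$E_inf_MPa * (et - ep) + params$E_1_MPa * (et - ep - ev)
    if (sig >= params$sigma_ult_MPa) { rupt <- TRUE; break }
    F_uN <- max(sig, 0) * A
    ev <- ev + h * (et - ep - ev) / params$tau_s
    ep <- ep + h * params$phi_per_MPa_s * max(0, sig - params$sigma_Y_MPa)
    xs <- xs + h * params$slip_rate_um_per_s_per_uN *
      max(0, F_uN - params$F_hold_uN)
  }
  specimen_state(state$t_s + dt, x_grip, xs, ev, ep, rupt)
}

# Random parameter set for trajectory comparisons.
random_params <- function() {
  mechanical_params(
    E_inf_MPa = runif(1, 10, 40),
    E_1_MPa = runif(1, 5, 20),
    tau_s = runif(1, 2, 8),
    sigma_Y_MPa = runif(1, 0.2, 1),
    phi_per_MPa_s = runif(1, 0, 2e-3),
    sigma_ult_MPa = 5,
    F_hold_uN = runif(1, 2000, 8000),
    slip_rate_um_per_s_per_uN = runif(1, 0, 3e-4)
  )
}

# Worst relative force error of evolve_specimen() vs the Euler oracle
# along a shared random staircase trajectory.
oracle_rel_err <- function(params, geom = default_geom(), n_steps = 20,
                           dt = 2) {
  sa <- specimen_state(); sb <- specimen_state()
  targets <- cumsum(runif(n_steps, 5, 25))
  fa <- fb <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    sa <- evolve_specimen(sa, geom, params, targets[k], dt)
    sb <- euler_oracle(sb, geom, params, targets[k], dt)
    fa[k] <- specimen_force(sa, geom, params)
    fb[k] <- specimen_force(sb, geom, params)
  }
  max(abs(fa - fb)) / max(fb)
}

# Calibrated virtual instrument around a given specimen.
calibrated_instrument <- function(geom = default_geom(),
                                  params = mechanical_params(),
                                  cell = load_cell_spec(),
                                  actuator = actuator_spec(),
                                  camera = camera_config(),
                                  cal_seed = 99) {
  inst <- virtual_instrument(actuator = actuator, load_cell = cell,
                             camera = camera, geom = geom, params = params)
  calibrate_instrument(inst, mass_g = 5, seed = cal_seed)
}

# Full optical-pathway modulus recovery: slow ramp on an elastic (phi = 0)
# specimen, landmark tracking, stress-strain curve, modulus over the best
# linear window. Returns recovered and true E plus the pieces.
recover_modulus <- function(E_inf, E_1 = E_inf / 2, tau = 4, seed = 1,
                            n_steps = 45, wait_s = 2, slip = FALSE,
                            span_steps = 25) {
  params <- mechanical_params(E_inf_MPa = E_inf, E_1_MPa = E_1, tau_s = tau,
                              sigma_Y_MPa = 4.9, phi_per_MPa_s = 0,
                              sigma_ult_MPa = 5)
  if (slip) {
    params$F_hold_uN <- 2000
    params$slip_rate_um_per_s_per_uN <- 2e-4
  }
  geom <- default_geom()
  inst <- calibrated_instrument(geom = geom, params = params,
                                cal_seed = seed + 1000)
  config <- experiment_config("ramp", distance_um = n_steps * 5,
                              step_size_um = 5, wait_time_s = wait_s,
                              seed = seed)
  log <- run_ramp(config, inst)
  track <- track_landmarks(log$frames)
  lmk <- landmark_strain(track)
  grp <- grip_strain(log, L0_um = geom$gauge_length_um)
  series <- strain_series(lmk, grp)
  curve <- stress_strain_curve(log$records$force_uN,
                               series$landmark_strain_pct, geom)
  region <- select_linear_region(curve, span_steps = span_steps)
  grip_curve <- stress_strain_curve(log$records$force_uN,
                                    series$grip_strain_pct, geom)
  list(E_landmark = youngs_modulus(curve, region),
       E_grip = youngs_modulus(grip_curve, region),
       E_true = E_inf, log = log, series = series, curve = curve,
       region = region, geom = geom)
}
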