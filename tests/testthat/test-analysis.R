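test_that("stress conversion uses the exact uN/um^2 = MPa identity", {
  geomp <- specimen_geometry("prismatic", gauge_length_um = 1000,
                             thickness_um = 100, width_um = 1000)
  expect_identical(stress_series(1e5, geomp), 1)
  expect_identical(stress_series(0, geomp), 0)
  geomc <- specimen_geometry("cylindrical", gauge_length_um = 1000,
                             radius_um = 250)
  expect_equal(stress_series(196350, geomc), 1.0, tolerance = 1e-5)
})

test_that("linear-region selection lands inside the linear segment", {
  geom <- specimen_geometry("prismatic", gauge_length_um = 1000,
                            thickness_um = 100, width_um = 1000)
  # exactly linear curve: earliest window wins at R^2 = 1
  eps <- seq(0.1, 10, by = 0.1)
  lin <- stress_strain_curve(eps * 1e4, eps, geom)
  r <- select_linear_region(lin, span_steps = 50)
  expect_identical(r$start, 1L)
  expect_equal(r$r_squared, 1)

  # toe + linear + softening: the window avoids both nonlinear ends
  toe <- 0.02 * (1:20)^2                     # concave-up settling
  mid <- toe[20] + 0.2 * (1:60)              # linear
  soft <- mid[60] + 0.2 * (1:30) - 0.004 * (1:30)^2  # softening
  sig <- c(toe, mid, soft)
  curve <- stress_strain_curve(sig * 1e5, seq_along(sig) * 0.1, geom)
  r2 <- select_linear_region(curve, span_steps = 40)
  expect_gte(r2$start, 20)
  expect_lte(r2$end, 85)

  expect_error(select_linear_region(lin, span_steps = 200),
               class = "microext_region_error")
})

test_that("linear regions beyond 20% strain trigger the strain-cap warning", {
  geom <- specimen_geometry("prismatic", gauge_length_um = 1000,
                            thickness_um = 100, width_um = 1000)
  eps <- seq(1, 30, by = 1)
  curve <- stress_strain_curve(eps * 1e4, eps, geom)
  expect_warning(select_linear_region(curve, span_steps = 30),
                 regexp = "20% strain")
})

test_that("Young's modulus follows the two-point definition", {
  geom <- specimen_geometry("prismatic", gauge_length_um = 1000,
                            thickness_um = 100, width_um = 1000)
  # delta sigma = 1 MPa over delta eps = 10% -> 10 MPa
  curve <- stress_strain_curve(c(0, 1e5), c(0, 10), geom)
  expect_equal(youngs_modulus(curve), 10)
  # least-squares option agrees on noiseless data
  curve3 <- stress_strain_curve(c(0, 5e4, 1e5), c(0, 5, 10), geom)
  expect_equal(youngs_modulus(curve3, method = "ls"), 10, tolerance = 1e-9)
  flat <- stress_strain_curve(c(0, 1e5), c(5, 5), geom)
  expect_error(youngs_modulus(flat), class = "microext_invalid_region")
})

test_that("rupture detection flags the sudden force drop", {
  expect_identical(detect_rupture(c(10, 20, 30, 40)), NA_integer_)
  f <- c(90, 100, 105, 12, 5)
  expect_identical(detect_rupture(f), 4L)  # 12 vs running max 105: -88.6%
  expect_identical(detect_rupture(numeric(0)), NA_integer_)
  # threshold sensitivity: a 30% dip is not rupture at drop_frac 0.5
  expect_identical(detect_rupture(c(100, 70, 110)), NA_integer_)
  expect_identical(detect_rupture(c(100, 70, 110), drop_frac = 0.25), 2L)
})

test_that("rupture step and ultimate stress recover the simulated truth", {
  geom <- default_geom()
  p <- mechanical_params(sigma_ult_MPa = 2.0, sigma_Y_MPa = 1.9,
                         phi_per_MPa_s = 0)
  inst <- calibrated_instrument(geom = geom, params = p,
                                cell = quiet_cell())
  cfg <- experiment_config("ramp", distance_um = 600, step_size_um = 5,
                           wait_time_s = 0.2, capture_frames = FALSE,
                           seed = 12)
  log <- run_ramp(cfg, inst)
  f <- log$records$force_uN
  # detection coincides with the simulator's rupture (first zero force)
  expect_identical(detect_rupture(f), which(f == 0)[1])
  # ultimate stress within one-step discretization of sigma_ult
  A <- cross_section_area(geom)
  step_sigma <- (p$E_inf_MPa + p$E_1_MPa) * 5 / geom$gauge_length_um
  expect_equal(ultimate_stress(f, geom), 2.0, tolerance = step_sigma / 2.0)
  # no rupture, no flag -> NA; boundary drop at step 2 keeps first force
  expect_true(is.na(ultimate_stress(c(10, 20, 30), geom)))
  expect_equal(ultimate_stress(c(100, 1, 1), geom), 100 / A)
})

test_that("yield onset is absent on linear curves and recovered on plastic ones", {
  geom <- default_geom()
  eps <- seq(0.1, 10, by = 0.1)
  lin <- stress_strain_curve(eps * 1e4, eps, geom)
  region <- list(start = 1L, end = 50L)
  y <- yield_onset(lin, region)
  expect_true(is.na(y$step))

  # slow ramp on a yielding specimen: onset stress near sigma_Y = 1 MPa
  p <- mechanical_params(E_inf_MPa = 20, E_1_MPa = 10, tau_s = 5,
                         sigma_Y_MPa = 1, phi_per_MPa_s = 5e-3,
                         sigma_ult_MPa = 2.5)
  inst <- calibrated_instrument(params = p, cell = quiet_cell())
  cfg <- experiment_config("ramp", distance_um = 400, step_size_um = 5,
                           wait_time_s = 6.7, capture_frames = FALSE,
                           seed = 13)
  log <- run_ramp(cfg, inst)
  # strain from the true tissue state (optical pathway tested elsewhere)
  strain <- (log$records$position_nm / 1000) / geom$gauge_length_um * 100
  curve <- stress_strain_curve(log$records$force_uN, strain, geom)
  reg <- select_linear_region(curve, span_steps = 25)
  yy <- yield_onset(curve, reg, tolerance_frac = 0.03)
  expect_false(is.na(yy$step))
  expect_equal(yy$yield_stress_MPa, 1.0, tolerance = 0.1)

  # zero tolerance flags the first wiggle on noisy-but-linear data
  withr::with_seed(14, {
    noisy <- stress_strain_curve(eps * 1e4 * (1 + rnorm(100, 0, 1e-4)),
                                 eps, geom)
  })
  y0 <- yield_onset(noisy, region, tolerance_frac = 0)
  expect_false(is.na(y0$step))
})

test_that("windowed creep rates tile the duration and reproduce arithmetic", {
  const <- tibble::tibble(time_s = seq(0, 900, by = 10),
                          landmark_um = 5, grip_um = 7)
  cp <- creep_rates(const, window_s = 300)
  expect_identical(nrow(cp), 3L)
  expect_true(all(cp$landmark_rate_um_per_s == 0))
  expect_true(all(cp$grip_rate_um_per_s == 0))
  # windows tile without overlap
  expect_equal(cp$t_start_s[-1], cp$t_end_s[-3])

  lin <- tibble::tibble(time_s = seq(0, 900, by = 10),
                        landmark_um = seq(0, 900, by = 10) / 100,
                        grip_um = seq(0, 900, by = 10) / 100)
  cp2 <- creep_rates(lin, window_s = 300)
  expect_equal(cp2$landmark_rate_um_per_s, rep(0.01, 3))  # 3 um per 300 s

  expect_error(creep_rates(lin, window_s = 0),
               class = "microext_invalid_window")
  expect_error(creep_rates(lin[1:3, ], window_s = 300),
               class = "microext_invalid_window")
})

test_that("slippage diagnosis separates slip-dominated runs from clean ones", {
  # figures' printed pair: grip 5.19% vs landmark 0.28% -> slip 4.91 pp
  s <- tibble::tibble(step = 1:2,
                      landmark_strain_pct = c(0.1, 0.28),
                      grip_strain_pct = c(0.5, 5.19))
  d <- slippage_diagnosis(s)
  expect_equal(tail(d$per_step$slip_strain_pct, 1), 4.91)
  expect_identical(d$verdict, "slip-dominated")

  # the onion case: actuator 163% vs junctions 19.1%
  onion <- tibble::tibble(step = 1, landmark_strain_pct = 19.05,
                          grip_strain_pct = 163)
  expect_identical(slippage_diagnosis(onion)$verdict, "slip-dominated")

  eq <- tibble::tibble(step = 1:2, landmark_strain_pct = c(1, 2),
                       grip_strain_pct = c(1, 2))
  d2 <- slippage_diagnosis(eq)
  expect_identical(d2$verdict, "none")
  expect_true(all(d2$per_step$slip_strain_pct == 0))

  bad <- tibble::tibble(step = 1, landmark_strain_pct = 5,
                        grip_strain_pct = 2)
  expect_warning(slippage_diagnosis(bad), regexp = "negative slip")
})

test_that("grip-pathway analysis underestimates the modulus when slip is present", {
  res <- recover_modulus(E_inf = 25, seed = 41, slip = TRUE, n_steps = 40)
  expect_lt(res$E_grip, res$E_landmark)
  # the grip pathway is the badly biased one (strain overestimated)
  expect_lt(res$E_grip, 0.6 * res$E_true)
  # the landmark pathway stays in the right range despite rate transients
  expect_lt(abs(res$E_landmark - res$E_true) / res$E_true, 0.1)
})

test_that("tidy and glance expose the summary in broom shape", {
  geom <- default_geom()
  eps <- seq(0.1, 8, by = 0.1)
  curve <- stress_strain_curve(eps * 1e4, eps, geom)
  ms <- mechanical_summary(curve, eps * 1e4, geom, span_steps = 30)
  td <- tidy(ms)
  expect_identical(names(td), c("quantity", "value", "unit"))
  gl <- glance(ms)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$youngs_modulus_MPa, ms$youngs_modulus_MPa)
})
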