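#' Mechanical parameters of the virtual specimen
#'
#' The constitutive model is a standard linear solid (equilibrium spring
#' `E_inf_MPa` in parallel with a Maxwell branch `E_1_MPa`--`tau_s`) in
#' series conceptually with a Lockhart/Bingham plastic element: plastic
#' strain accumulates at rate \eqn{\Phi \cdot \max(0, \sigma - \sigma_Y)}
#' once stress exceeds the yield threshold. Grip slip is a threshold
#' viscous element: the specimen slides within its mounting tags at rate
#' `slip_rate_um_per_s_per_uN * max(0, F - F_hold_uN)`. Rupture is brittle:
#' when stress reaches `sigma_ult_MPa` the transmitted force drops to zero
#' permanently.
#'
#' Defaults describe a soft, dark-grown seedling axis tested on a 10 g
#' load cell; slip is disabled (`F_hold_uN = Inf`) unless requested.
#'
#' @param E_inf_MPa Equilibrium elastic modulus (MPa).
#' @param E_1_MPa Transient-branch modulus (MPa).
#' @param tau_s Retardation time of the transient branch (s).
#' @param sigma_Y_MPa Yield stress (MPa); creep starts above it.
#' @param phi_per_MPa_s Lockhart extensibility (1 / (MPa s)).
#' @param sigma_ult_MPa Ultimate (rupture) stress (MPa).
#' @param F_hold_uN Grip holding force (uN); slip occurs above it.
#' @param slip_rate_um_per_s_per_uN Slip compliance above `F_hold_uN`.
#' @return An object of class `mechanical_params`.
#' @export
mechanical_params <- function(E_inf_MPa = 20,
                              E_1_MPa = 10,
                              tau_s = 5,
                              sigma_Y_MPa = 1,
                              phi_per_MPa_s = 2e-4,
                              sigma_ult_MPa = 2.5,
                              F_hold_uN = Inf,
                              slip_rate_um_per_s_per_uN = 0) {
  if (E_inf_MPa <= 0 || E_1_MPa <= 0 || tau_s <= 0 || sigma_ult_MPa <= 0) {
    stop_microext("moduli, tau_s and sigma_ult_MPa must all be > 0.",
                  "microext_invalid_params")
  }
  if (sigma_Y_MPa < 0 || phi_per_MPa_s < 0 ||
      F_hold_uN < 0 || slip_rate_um_per_s_per_uN < 0) {
    stop_microext("sigma_Y_MPa, phi_per_MPa_s and slip parameters must be >= 0.",
                  "microext_invalid_params")
  }
  if (sigma_ult_MPa <= sigma_Y_MPa) {
    stop_microext("sigma_ult_MPa must exceed sigma_Y_MPa.",
                  "microext_invalid_params")
  }
  structure(
    list(E_inf_MPa = E_inf_MPa, E_1_MPa = E_1_MPa, tau_s = tau_s,
         sigma_Y_MPa = sigma_Y_MPa, phi_per_MPa_s = phi_per_MPa_s,
         sigma_ult_MPa = sigma_ult_MPa, F_hold_uN = F_hold_uN,
         slip_rate_um_per_s_per_uN = slip_rate_um_per_s_per_uN),
    class = "mechanical_params"
  )
}

#' Material state of the virtual specimen
#'
#' Tracks imposed grip displacement `x_grip_um`, cumulative grip slip
#' `x_slip_um`, the internal viscous-branch strain `eps_v`, accumulated
#' plastic strain `eps_p`, elapsed time and the (one-way) rupture flag.
#' Slip and plastic strain are monotone non-decreasing along any
#' trajectory; once ruptured the transmitted force is identically zero.
#'
#' @param t_s,x_grip_um,x_slip_um,eps_v,eps_p,ruptured Initial values.
#' @return An object of class `specimen_state`.
#' @export
specimen_state <- function(t_s = 0, x_grip_um = 0, x_slip_um = 0,
                           eps_v = 0, eps_p = 0, ruptured = FALSE) {
  structure(
    list(t_s = t_s, x_grip_um = x_grip_um, x_slip_um = x_slip_um,
         eps_v = eps_v, eps_p = eps_p, ruptured = isTRUE(ruptured)),
    class = "specimen_state"
  )
}

# stress (MPa, unclamped) from a raw state vector; eps_total is the tissue
# strain (grip displacement minus slip, over L0)
.specimen_sigma <- function(x_grip_um, x_slip_um, eps_v, eps_p, geom, params) {
  eps_total <- (x_grip_um - x_slip_um) / geom$gauge_length_um
  params$E_inf_MPa * (eps_total - eps_p) +
    params$E_1_MPa * (eps_total - eps_p - eps_v)
}

#' Force transmitted by the specimen
#'
#' \eqn{\varepsilon_{tot} = (x_{grip} - x_{slip})/L_0};
#' \eqn{\sigma = E_\infty(\varepsilon_{tot} - \varepsilon_p) +
#' E_1(\varepsilon_{tot} - \varepsilon_p - \varepsilon_v)};
#' \eqn{F = \sigma A} (1 uN/um^2 = 1 MPa). The force is clamped at zero
#' (tag mounting transmits no compression) and is identically zero after
#' rupture.
#'
#' @param state A [specimen_state()].
#' @param geom A [specimen_geometry()].
#' @param params A [mechanical_params()].
#' @return Force in uN.
#' @export
specimen_force <- function(state, geom, params) {
  if (state$ruptured) return(0)
  stopifnot(all(is.finite(c(state$x_grip_um, state$x_slip_um,
                            state$eps_v, state$eps_p))))
  sigma <- .specimen_sigma(state$x_grip_um, state$x_slip_um,
                           state$eps_v, state$eps_p, geom, params)
  max(sigma, 0) * cross_section_area(geom)
}

#' Advance the specimen state under an imposed grip displacement
#'
#' The grip displacement is set to `x_grip_target_um` at the start of the
#' interval and held (a stepper step is near-instant compared to the wait
#' between steps); the internal laws are then integrated over `dt_s`:
#' \deqn{\dot\varepsilon_v = (\varepsilon_{tot} - \varepsilon_p - \varepsilon_v)/\tau}
#' \deqn{\dot\varepsilon_p = \Phi \max(0, \sigma - \sigma_Y)}
#' \deqn{\dot x_{slip} = k_{slip} \max(0, F - F_{hold})}
#' Rupture is latched as soon as \eqn{\sigma \ge \sigma_{ult}}; afterwards
#' the transmitted force is zero and the internal state is frozen.
#'
#' Integration uses a fixed-substep explicit midpoint update with the
#' substep bounded by `tau_s / 50` and by the plastic and slip rate
#' constants, so the result is deterministic and agrees with a fine-step
#' reference integration to well under 0.1 percent.
#'
#' @inheritParams specimen_force
#' @param x_grip_target_um Grip displacement held over the interval (um).
#' @param dt_s Interval length in seconds (> 0).
#' @return The updated `specimen_state`.
#' @export
evolve_specimen <- function(state, geom, params, x_grip_target_um, dt_s) {
  if (!is.numeric(dt_s) || length(dt_s) != 1 || !is.finite(dt_s) || dt_s <= 0) {
    stop_microext("`dt_s` must be a single positive number.",
                  "microext_invalid_dt")
  }
  A <- cross_section_area(geom)
  L0 <- geom$gauge_length_um
  x_grip <- x_grip_target_um
  if (state$ruptured) {
    state$x_grip_um <- x_grip
    state$t_s <- state$t_s + dt_s
    return(state)
  }

  # substep caps: viscous branch, plastic stiffness relaxation, slip
  h <- params$tau_s / 50
  if (params$phi_per_MPa_s > 0) {
    h <- min(h, 0.02 / (params$phi_per_MPa_s *
                          (params$E_inf_MPa + params$E_1_MPa)))
  }
  if (params$slip_rate_um_per_s_per_uN > 0 && is.finite(params$F_hold_uN)) {
    k_uN_per_um <- (params$E_inf_MPa + params$E_1_MPa) * A / L0
    h <- min(h, 0.02 / (params$slip_rate_um_per_s_per_uN * k_uN_per_um))
  }
  n_sub <- max(1L, ceiling(dt_s / h))
  h <- dt_s / n_sub

  eps_v <- state$eps_v; eps_p <- state$eps_p; x_slip <- state$x_slip_um
  ruptured <- FALSE

  rates <- function(eps_v, eps_p, x_slip) {
    sigma <- .specimen_sigma(x_grip, x_slip, eps_v, eps_p, geom, params)
    F_uN <- max(sigma, 0) * A
    c(v = ((x_grip - x_slip) / L0 - eps_p - eps_v) / params$tau_s,
      p = params$phi_per_MPa_s * max(0, sigma - params$sigma_Y_MPa),
      s = params$slip_rate_um_per_s_per_uN * max(0, F_uN - params$F_hold_uN))
  }

  # rupture check at t0+ (the grip step itself can take sigma past ultimate)
  sigma0 <- .specimen_sigma(x_grip, x_slip, eps_v, eps_p, geom, params)
  if (sigma0 >= params$sigma_ult_MPa) ruptured <- TRUE

  if (!ruptured) {
    for (i in seq_len(n_sub)) {
      r1 <- rates(eps_v, eps_p, x_slip)
      r2 <- rates(eps_v + 0.5 * h * r1[["v"]],
                  eps_p + 0.5 * h * r1[["p"]],
                  x_slip + 0.5 * h * r1[["s"]])
      eps_v <- eps_v + h * r2[["v"]]
      eps_p <- eps_p + h * r2[["p"]]
      x_slip <- x_slip + h * r2[["s"]]
      sigma <- .specimen_sigma(x_grip, x_slip, eps_v, eps_p, geom, params)
      if (sigma >= params$sigma_ult_MPa) {
        ruptured <- TRUE
        break
      }
    }
  }

  specimen_state(t_s = state$t_s + dt_s, x_grip_um = x_grip,
                 x_slip_um = x_slip, eps_v = eps_v, eps_p = eps_p,
                 ruptured = ruptured)
}

#' Lab positions of material landmarks
#'
#' Maps material coordinates (fractions of the gauge length) to lab
#' positions, so that the rendered landmark separation reflects the true
#' tissue strain \eqn{(x_{grip} - x_{slip})/L_0} and excludes grip slip;
#' grip-tag separation, in contrast, grows with the full `x_grip_um`.
#'
#' @inheritParams specimen_force
#' @param material_fracs Sorted fractions in \[0, 1\] along the gauge length.
#' @return Numeric vector of lab positions in um (0 = fixed, sensor-side grip).
#' @export
landmark_positions <- function(state, geom, material_fracs) {
  if (any(material_fracs < 0 | material_fracs > 1)) {
    stop_microext("`material_fracs` must lie within [0, 1].",
                  "microext_invalid_fracs")
  }
  if (is.unsorted(material_fracs)) {
    stop_microext("`material_fracs` must be sorted increasing.",
                  "microext_invalid_fracs")
  }
  eps_tissue <- (state$x_grip_um - state$x_slip_um) / geom$gauge_length_um
  material_fracs * geom$gauge_length_um * (1 + eps_tissue)
}

#' Grip-tag separation
#'
#' The distance between the two mounting tags: \eqn{L_0 + x_{grip}}. This
#' is the actuator-based length the grip-strain pathway sees, inflated by
#' slip relative to the landmark pathway.
#'
#' @inheritParams specimen_force
#' @return Separation in um.
#' @export
grip_separation <- function(state, geom) {
  geom$gauge_length_um + state$x_grip_um
}
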