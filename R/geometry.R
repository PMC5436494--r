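#' Coiled tubular reactor geometry
#'
#' The reactor is a coiled tube characterised by its internal volume, tube
#' internal diameter and (for Dean-number work) the coil winding diameter.
#' Tube length is derived as `L = V / (pi d_t^2 / 4)`.
#'
#' @param volume_mL Internal volume in mL (default 5).
#' @param d_t_mm Tube internal diameter in mm (default 0.79).
#' @param d_c_mm Coil winding diameter in mm. No default: it is required only
#'   for Dean-number calculations and must be supplied there.
#' @return An object of class `reactor_geometry` with SI fields
#'   `volume_m3`, `d_t_m`, `d_c_m`, `area_m2`, `length_m` alongside the
#'   interface units.
#' @examples
#' geom <- reactor_geometry()
#' geom$length_m # ~10.2 m for the 5 mL, 0.79 mm ID coil
#' @export
reactor_geometry <- function(volume_mL = 5, d_t_mm = 0.79, d_c_mm = NA_real_) {
  check_number(volume_mL, "volume_mL", lower = 1e-12)
  check_number(d_t_mm, "d_t_mm", lower = 1e-9)
  if (!is.na(d_c_mm)) {
    check_number(d_c_mm, "d_c_mm", lower = 1e-9)
    if (d_c_mm < d_t_mm) abort_config("Coil diameter `d_c_mm` must be >= tube diameter `d_t_mm`.")
  }
  d_t_m <- d_t_mm * 1e-3
  area <- pi * d_t_m^2 / 4
  vol <- volume_mL * 1e-6
  structure(list(
    volume_mL = volume_mL, d_t_mm = d_t_mm, d_c_mm = d_c_mm,
    volume_m3 = vol, d_t_m = d_t_m, d_c_m = d_c_mm * 1e-3,
    area_m2 = area, length_m = vol / area
  ), class = "reactor_geometry")
}

#' Thermal expansion of the carrier solvent
#'
#' Pumps meter flow at ambient temperature; inside the heated coil the fluid
#' expands, raising the linear velocity by the factor
#' \eqn{\beta(T) = 1 + \alpha_v (T_1 - T_0)}.
#'
#' @param alpha_v Volumetric expansion coefficient (K^-1); default 1.1e-3,
#'   a standard value for ethanol near ambient conditions.
#' @param T0_C Ambient reference temperature in degC (default 25).
#' @return An object of class `thermal_expansion_model`.
#' @export
thermal_expansion_model <- function(alpha_v = 1.1e-3, T0_C = 25) {
  check_number(alpha_v, "alpha_v", lower = 0)
  check_number(T0_C, "T0_C")
  structure(list(alpha_v = alpha_v, T0_C = T0_C), class = "thermal_expansion_model")
}

#' Thermal expansion factor beta(T)
#'
#' @param model A [thermal_expansion_model()].
#' @param T1_C Reactor temperature in degC (vectorized).
#' @return Dimensionless beta; exactly 1 at `T1_C = T0_C`.
#' @export
thermal_expansion_factor <- function(model, T1_C) {
  if (any(T1_C < model$T0_C - 50)) {
    abort_parameter("`T1_C` is more than 50 K below the ambient reference; outside the sanity window.")
  }
  beta <- 1 + model$alpha_v * (T1_C - model$T0_C)
  if (any(beta <= 0)) abort_parameter("Thermal expansion factor beta must be positive.")
  beta
}

# mL/min -> m^3/s
ml_min_to_m3_s <- function(q) q * 1e-6 / 60

#' Mean velocity in the coil during a linear ramp
#'
#' For a linear deceleration of the total pumped flow,
#' \eqn{u(t) = \beta(T) (u_o - \alpha_u t)} where \eqn{u_o} is the velocity at
#' ramp onset and \eqn{\alpha_u} the velocity deceleration corresponding to
#' the volumetric ramp rate.
#'
#' @param geom A [reactor_geometry()].
#' @param Q_start_mL_min Total pumped flow at ramp onset (mL min^-1).
#' @param alpha_mL_min2 Volumetric deceleration rate (mL min^-2); 0 for
#'   constant flow.
#' @param t_min Time since ramp onset (min); negative times lie in the
#'   pre-ramp hold at constant flow. Vectorized.
#' @param beta Thermal expansion factor (default 1).
#' @return Mean velocity in m s^-1.
#' @export
velocity_at_time <- function(geom, Q_start_mL_min, alpha_mL_min2 = 0, t_min = 0,
                             beta = 1) {
  q <- Q_start_mL_min - alpha_mL_min2 * pmax(t_min, 0)
  if (any(q <= 0)) {
    abort_schedule("Scheduled flow is non-positive: the ramp overruns Q = 0.")
  }
  beta * ml_min_to_m3_s(q) / geom$area_m2
}

#' Residence time of a sample taken at clock time t
#'
#' A fluid element leaving the coil at time `t` has swept the full reactor
#' volume. With pumped flow `Q(t') = Q0 - alpha t'` during the ramp (and `Q0`
#' during the pre-ramp hold) and thermal expansion `beta`, the element's
#' residence time solves
#' \deqn{\int_{t-\tau}^{t} Q(t')\,dt' = V/\beta,}
#' a quadratic in \eqn{\tau} whose physical root is the smaller positive one.
#' At constant flow this reduces to \eqn{\tau = V/(\beta Q)}.
#'
#' @inheritParams velocity_at_time
#' @param t_min Sampling (clock) time since ramp onset, in minutes.
#' @param hold_min Duration of the pre-ramp constant-flow hold (min); fluid
#'   elements may have entered during the hold. Default `Inf` (fully
#'   developed steady hold).
#' @param method `"closed_form"` (quadratic root) or `"numeric"` (bisection on
#'   the sweep integral; validation route).
#' @return Residence time in minutes (vectorized over `t_min`).
#' @examples
#' geom <- reactor_geometry() # 5 mL
#' residence_time(geom, Q_start_mL_min = 10, alpha_mL_min2 = 0, t_min = 0) # 0.5 min
#' residence_time(geom, 10, 0.836, t_min = 6) # ~0.931 min
#' @export
residence_time <- function(geom, Q_start_mL_min, alpha_mL_min2 = 0, t_min,
                           beta = 1, hold_min = Inf,
                           method = c("closed_form", "numeric")) {
  method <- match.arg(method)
  check_number(Q_start_mL_min, "Q_start_mL_min", lower = 1e-12)
  check_number(alpha_mL_min2, "alpha_mL_min2", lower = 0)
  v_eff <- geom$volume_mL / beta
  q0 <- Q_start_mL_min
  a <- alpha_mL_min2
  vapply(t_min, function(t) {
    if (t < 0) abort_schedule("Sampling time must be >= ramp onset (t >= 0).")
    if (q0 - a * t <= 0) abort_schedule("Scheduled flow is non-positive at the sampling time.")
    if (method == "numeric") {
      return(residence_time_numeric(v_eff, q0, a, t, hold_min))
    }
    swept_in_ramp <- q0 * t - a * t^2 / 2
    if (swept_in_ramp >= v_eff) {
      if (a == 0) return(v_eff / q0)
      disc <- (q0 - a * t)^2 + 2 * a * v_eff
      if (disc < 0) abort_schedule("No real residence-time root: reactor not fully swept.")
      # smaller positive root of (a/2) tau^2 + (q0 - a t) tau - v_eff = 0
      (-(q0 - a * t) + sqrt(disc)) / a
    } else {
      tau <- t + (v_eff - swept_in_ramp) / q0
      if (tau - t > hold_min) {
        abort_schedule("Element would have entered before the pre-ramp hold: reactor not fully swept.")
      }
      tau
    }
  }, numeric(1))
}

# Bisection on the sweep integral; oracle for the closed form.
residence_time_numeric <- function(v_eff, q0, a, t, hold_min) {
  pumped <- function(tp) ifelse(tp <= 0, q0 * tp, q0 * tp - a * tp^2 / 2)
  g <- function(tau) pumped(t) - pumped(t - tau) - v_eff
  upper <- t + min(hold_min, v_eff / q0 * 2 + 1)
  if (g(upper) < 0) abort_schedule("Reactor not fully swept within the schedule.")
  stats::uniroot(g, lower = 0, upper = upper, tol = 1e-13)$root
}

#' Inlet concentrations from pump flows and stock solutions
#'
#' Pump P1 delivers substrate stock, P2 pure solvent make-up, P3 nucleophile
#' stock. Inlet concentrations follow from flow-weighted dilution
#' `C_i0 = stock_i * Q_i / Q_total`; they are constant within a ramp because
#' the pump flow ratios are held constant.
#'
#' @param Q_P1,Q_P2,Q_P3 Pump flows (mL min^-1, any common unit).
#' @param stock_C1_M,stock_C2_M Stock concentrations (M) of substrate (P1)
#'   and nucleophile (P3).
#' @return Tibble with `C1_0_M`, `C2_0_M`, `equivalents`.
#' @export
inlet_concentrations <- function(Q_P1, Q_P2, Q_P3, stock_C1_M, stock_C2_M) {
  q_tot <- Q_P1 + Q_P2 + Q_P3
  if (q_tot <= 0) abort_config("Total flow must be positive.")
  if (any(c(Q_P1, Q_P2, Q_P3) < 0) || any(c(stock_C1_M, stock_C2_M) < 0)) {
    abort_config("Pump flows and stock concentrations must be non-negative.")
  }
  c1 <- stock_C1_M * Q_P1 / q_tot
  c2 <- stock_C2_M * Q_P3 / q_tot
  tibble::tibble(C1_0_M = c1, C2_0_M = c2,
    equivalents = ifelse(c1 > 0, c2 / c1, ifelse(c2 > 0, Inf, 0)))
}

#' Pump flow fractions that realise a target inlet composition
#'
#' Solves the dilution relations for the P1/P2/P3 flow fractions giving a
#' target substrate inlet concentration and nucleophile:substrate molar
#' equivalents.
#'
#' @param equivalents Target molar equivalents `C2_0 / C1_0`.
#' @param C1_0_M Target substrate inlet concentration (M).
#' @param stock_C1_M,stock_C2_M Stock concentrations (M).
#' @return Tibble with fractions `f_P1`, `f_P2`, `f_P3` (summing to 1).
#' @export
pump_fractions <- function(equivalents, C1_0_M, stock_C1_M, stock_C2_M) {
  if (C1_0_M <= 0 && any(equivalents > 0)) {
    abort_config("Nonzero equivalents requested with zero substrate inlet concentration.")
  }
  f1 <- C1_0_M / stock_C1_M
  f3 <- equivalents * C1_0_M / stock_C2_M
  f2 <- 1 - f1 - f3
  if (any(f1 < 0) || any(f3 < 0) || any(f2 < 0)) {
    abort_config("Requested composition is infeasible with these stocks (negative pump fraction).")
  }
  tibble::tibble(equivalents = equivalents, f_P1 = f1, f_P2 = f2, f_P3 = f3)
}
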