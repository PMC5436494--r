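# Step-response (F-curve) analysis of the coil: forward model and kappa
# estimation.

#' Closed-vessel F-curve model
#'
#' Normalized step response of a closed (Danckwerts) dispersed plug-flow
#' vessel as a function of dimensionless time `theta = t / tau` and the
#' dispersion number `Pe = D/(uL)`. For `Pe < 0.02` (all coil operating
#' points of practical interest here) the closed-vessel response is computed
#' from its Gaussian small-dispersion limit with the exact closed-vessel
#' variance `sigma^2 = 2 Pe - 2 Pe^2 (1 - exp(-1/Pe))`; for larger `Pe` the
#' Danckwerts closed-closed PDE is solved by method of lines.
#'
#' @param theta Dimensionless time grid (>= 0).
#' @param Pe Dispersion number `D/(uL)` (> 0).
#' @param method `"auto"` (default), `"analytic"` or `"numeric"`.
#' @param n_cells Spatial cells for the numeric branch.
#' @return Numeric vector `F(theta)` in \[0, 1\].
#' @export
f_curve_model <- function(theta, Pe, method = c("auto", "analytic", "numeric"),
                          n_cells = 300) {
  method <- match.arg(method)
  if (Pe <= 0) abort_parameter("`Pe` must be positive.")
  if (method == "auto") method <- if (Pe < 0.02) "analytic" else "numeric"
  if (method == "analytic") {
    sigma2 <- 2 * Pe - 2 * Pe^2 * (1 - exp(-1 / Pe))
    stats::pnorm((theta - 1) / sqrt(sigma2))
  } else {
    f_curve_numeric(theta, Pe, n_cells)
  }
}

# Danckwerts closed-closed step response by method of lines (central
# differencing; cell Peclet number Delta/Pe must stay < 2).
f_curve_numeric <- function(theta, Pe, n_cells = 300) {
  dz <- 1 / n_cells
  if (dz / Pe > 2) {
    rlang::warn("Cell Peclet number > 2: increase `n_cells` or use the analytic branch.")
  }
  rhs <- function(t, y, p) {
    flux <- c(1, (y[-n_cells] + y[-1]) / 2 - Pe * diff(y) / dz, y[n_cells])
    list(-diff(flux) / dz)
  }
  times <- sort(unique(c(0, theta)))
  sol <- deSolve::lsoda(y = rep(0, n_cells), times = times, func = rhs,
    parms = NULL, rtol = 1e-8, atol = 1e-10)
  out <- sol[match(theta, times), n_cells + 1]
  pmin(pmax(out, 0), 1)
}

#' Simulate a synthetic F-curve for a coil operating point
#'
#' Generates the normalized step response of the coil at mean velocity `u`
#' with the Taylor-Aris dispersion coefficient scaled by the coil dispersion
#' ratio `kappa`.
#'
#' @param geom A [reactor_geometry()].
#' @param fluid A [fluid_properties()].
#' @param u Mean velocity (m s^-1).
#' @param kappa Coil dispersion ratio in (0, 1].
#' @param times_s Sampling times (s); default a uniform grid spanning
#'   0.5-1.5 residence times.
#' @param n_points Grid size when `times_s` is NULL.
#' @return Tibble with `time_s`, `F`.
#' @export
simulate_f_curve <- function(geom, fluid, u, kappa, times_s = NULL,
                             n_points = 201) {
  tau <- geom$length_m / u
  if (is.null(times_s)) times_s <- seq(0.5 * tau, 1.5 * tau, length.out = n_points)
  D_s <- taylor_aris_dispersion(u, geom$d_t_m, fluid$D_m, kappa)
  Pe <- D_s / (u * geom$length_m)
  tibble::tibble(time_s = times_s, F = f_curve_model(times_s / tau, Pe))
}

#' Estimate the coil dispersion ratio from a measured F-curve
#'
#' Fits the closed-vessel axial-dispersion step response to a measured
#' F-curve by least squares over the dispersion number, converts the fitted
#' dispersion number to a dispersion coefficient `D_s = Pe u L`, and reports
#' \eqn{\kappa = (D_s - D_m) / (d_t^2 u^2 / (192 D_m))}, the ratio to the
#' straight-tube Taylor-Aris value at the same operating point.
#'
#' @param f_curve Tibble/data frame with columns `time_s` and `F`
#'   (normalized outlet step response, ~0 rising to ~1).
#' @param geom A [reactor_geometry()].
#' @param fluid A [fluid_properties()].
#' @param u Mean velocity (m s^-1) during the measurement.
#' @return List with `kappa`, `D_s`, `Pe`, `sse`.
#' @examples
#' geom <- reactor_geometry()
#' fl <- fluid_properties()
#' u <- geom$length_m / 360 # 6 min residence time
#' fc <- simulate_f_curve(geom, fl, u, kappa = 0.31)
#' estimate_kappa_from_f_curve(fc, geom, fl, u)$kappa
#' @export
estimate_kappa_from_f_curve <- function(f_curve, geom, fluid, u) {
  if (!all(c("time_s", "F") %in% names(f_curve))) {
    abort_data("F-curve must have columns `time_s` and `F`.")
  }
  fc <- dplyr::arrange(tibble::as_tibble(f_curve), .data$time_s)
  if (any(diff(fc$F) < -1e-3)) {
    abort_data("F-curve is not non-decreasing; cannot fit the step-response model.")
  }
  if (max(fc$F) < 0.95 || min(fc$F) > 0.05) {
    abort_data("F-curve is truncated: it must span ~0 to ~1 to resolve the front.")
  }
  tau <- geom$length_m / u
  theta <- fc$time_s / tau
  sse_of <- function(log10_pe) {
    sum((f_curve_model(theta, 10^log10_pe) - fc$F)^2)
  }
  opt <- stats::optimize(sse_of, interval = c(-7, 0.5), tol = 1e-10)
  Pe <- 10^opt$minimum
  D_s <- Pe * u * geom$length_m
  D_straight <- taylor_aris_dispersion(u, geom$d_t_m, fluid$D_m, kappa = 1)
  kappa <- (D_s - fluid$D_m) / (D_straight - fluid$D_m)
  if (opt$minimum < -6.5 || kappa < 1e-3) {
    rlang::warn(paste(
      "Fitted dispersion is at the resolution limit of the data (near-ideal",
      "plug-flow front); kappa ~ 0 is under-resolved."),
      class = "flowramp_resolution_warning")
    kappa <- max(kappa, 0)
  }
  list(kappa = kappa, D_s = D_s, Pe = Pe, sse = opt$objective)
}

#' Per-profile dispersion bias report for a fitted campaign
#'
#' For every ramp of a campaign, lumps the fitted second-order constants into
#' pseudo-first-order constants at the ramp's temperature and inlet
#' nucleophile concentration (`k12 = (k1 + k2) C_2,0` for substrate
#' consumption, `k34 = (k3 + k4) C_2,0` for over-reaction), evaluates the
#' small-dispersion rate-constant bias at a representative velocity, and
#' masks profiles whose reacting-component concentration range is too small
#' to inform the corresponding rate constants (the analogue of greyed cells
#' in a campaign bias table).
#'
#' @param table The campaign sample table used in the fit.
#' @param fit A [fit_kinetics()] result.
#' @param geom A [reactor_geometry()].
#' @param fluid A [fluid_properties()].
#' @param kappa Fixed dispersion ratio applied to all profiles (conservative
#'   default 0.15), or a [kappa_correlation()] to interpolate per profile
#'   (requires `d_c_mm` on the geometry).
#' @param mask_threshold Minimum concentration range, as a fraction of the
#'   substrate inlet concentration, for a profile to inform a rate constant.
#' @param coefficient Passed to [rate_constant_bias()].
#' @return Tibble with one row per ramp: lumped constants, `epsilon_12_pct`,
#'   `epsilon_34_pct`, and masking flags `masked_12`, `masked_34`.
#' @export
campaign_dispersion_report <- function(table, fit, geom = reactor_geometry(),
                                       fluid = fluid_properties(),
                                       kappa = 0.15, mask_threshold = 0.05,
                                       coefficient = c("printed", "taylor_aris")) {
  coefficient <- match.arg(coefficient)
  pars <- scheme_params(fit$scheme)
  per_ramp <- dplyr::group_by(table, .data$ramp_id, .data$equivalents, .data$temp_C)
  per_ramp <- dplyr::summarise(per_ramp,
    C1_0_M = .data$C1_0_M[1], C2_0_M = .data$C2_0_M[1],
    beta = if ("beta" %in% names(table)) .data$beta[1] else 1,
    Q_med = stats::median(.data$Q_total_mL_min),
    range_C1 = max(.data$C1_M) - min(.data$C1_M),
    range_C5 = max(.data$C5_M) - min(.data$C5_M),
    .groups = "drop")
  T_K <- celsius_to_kelvin(per_ramp$temp_C)
  k_at_T <- function(i) arrhenius_k(fit$scheme$steps[[i]]$params, T_K)
  k12 <- lumped_first_order(k_at_T(1), k_at_T(2), per_ramp$C2_0_M)
  k34 <- lumped_first_order(k_at_T(3), k_at_T(4), per_ramp$C2_0_M)
  u <- per_ramp$beta * ml_min_to_m3_s(per_ramp$Q_med) / geom$area_m2
  kap <- if (inherits(kappa, "kappa_correlation")) {
    kappa_from_correlation(dimensionless_groups(geom, fluid, u)$DeSc05, kappa)
  } else {
    rep(kappa, nrow(per_ramp))
  }
  eps12 <- suppressWarnings(rate_constant_bias(k12, geom$d_t_m, fluid$D_m, kap,
    coefficient = coefficient)$epsilon)
  eps34 <- suppressWarnings(rate_constant_bias(k34, geom$d_t_m, fluid$D_m, kap,
    coefficient = coefficient)$epsilon)
  dplyr::mutate(per_ramp,
    kappa = kap, u_m_s = u,
    k12_s1 = k12, k34_s1 = k34,
    epsilon_12_pct = 100 * eps12, epsilon_34_pct = 100 * eps34,
    masked_12 = .data$range_C1 < mask_threshold * .data$C1_0_M,
    masked_34 = .data$range_C5 < mask_threshold * .data$C1_0_M)
}
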