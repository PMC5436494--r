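#' Campaign design: ramp schedule, factorial levels and inlet targets
#'
#' Describes a full flow-ramp campaign: the reactor, the thermal expansion
#' model, one linear deceleration ramp repeated over a full factorial of
#' nucleophile equivalents and reactor temperatures, and the stock solutions
#' that realise the inlet compositions. Defaults reproduce the reference
#' 12-ramp design: equivalents 1.5/4/7 at 30/60/90/120 degC, total flow
#' decelerating 10 -> 1.5 mL min^-1 at 0.836 mL min^-2 with an HPLC injection
#' every 2 min from ramp onset.
#'
#' @param geometry A [reactor_geometry()].
#' @param thermal A [thermal_expansion_model()].
#' @param Q_start_mL_min,Q_end_mL_min Total flow at ramp start/end (mL min^-1).
#' @param alpha_mL_min2 Linear deceleration rate (mL min^-2).
#' @param injection_interval_min Time between HPLC injections (min).
#' @param hold_min Pre-ramp constant-flow hold (min); must be long enough that
#'   the first elements sampled entered under steady flow.
#' @param equivalents Nucleophile:substrate molar equivalents levels.
#' @param temperatures_C Reactor temperature levels (degC).
#' @param C1_0_M Substrate inlet concentration (M), constant across ramps.
#' @param stock_C1_M,stock_C2_M Stock concentrations (M) on pumps P1 and P3.
#' @param first_injection `"ramp_onset"` (default) or `"pre_ramp"`: whether the
#'   first sample of each ramp is drawn at ramp onset or at the end of the
#'   steady hold (same composition, same residence time; affects labelling
#'   only).
#' @return An object of class `campaign_design`.
#' @export
campaign_design <- function(geometry = reactor_geometry(),
                            thermal = thermal_expansion_model(),
                            Q_start_mL_min = 10, Q_end_mL_min = 1.5,
                            alpha_mL_min2 = 0.836,
                            injection_interval_min = 2,
                            hold_min = 2,
                            equivalents = c(1.5, 4, 7),
                            temperatures_C = c(30, 60, 90, 120),
                            C1_0_M = 0.1,
                            stock_C1_M = 0.5, stock_C2_M = 2.0,
                            first_injection = c("ramp_onset", "pre_ramp")) {
  first_injection <- match.arg(first_injection)
  check_number(Q_start_mL_min, "Q_start_mL_min", lower = 1e-9)
  check_number(Q_end_mL_min, "Q_end_mL_min", lower = 1e-9, upper = Q_start_mL_min)
  check_number(alpha_mL_min2, "alpha_mL_min2", lower = 0)
  if (injection_interval_min <= 0) abort_config("`injection_interval_min` must be > 0.")
  check_number(hold_min, "hold_min", lower = 0)
  check_number(C1_0_M, "C1_0_M", lower = 1e-12)
  if (alpha_mL_min2 == 0 && Q_end_mL_min != Q_start_mL_min) {
    abort_config("Zero ramp rate with Q_end != Q_start is inconsistent.")
  }
  # validate stock feasibility up front
  pump_fractions(max(equivalents), C1_0_M, stock_C1_M, stock_C2_M)
  structure(list(
    geometry = geometry, thermal = thermal,
    Q_start_mL_min = Q_start_mL_min, Q_end_mL_min = Q_end_mL_min,
    alpha_mL_min2 = alpha_mL_min2,
    injection_interval_min = injection_interval_min, hold_min = hold_min,
    equivalents = equivalents, temperatures_C = temperatures_C,
    C1_0_M = C1_0_M, stock_C1_M = stock_C1_M, stock_C2_M = stock_C2_M,
    first_injection = first_injection
  ), class = "campaign_design")
}

#' @export
print.campaign_design <- function(x, ...) {
  cat(sprintf(
    "<campaign_design>: %d ramps (%d equivalents x %d temperatures)\n  Q %g -> %g mL/min at %g mL/min^2, injections every %g min\n",
    length(x$equivalents) * length(x$temperatures_C),
    length(x$equivalents), length(x$temperatures_C),
    x$Q_start_mL_min, x$Q_end_mL_min, x$alpha_mL_min2, x$injection_interval_min))
  invisible(x)
}

ramp_duration_min <- function(design) {
  if (design$alpha_mL_min2 == 0) return(0)
  (design$Q_start_mL_min - design$Q_end_mL_min) / design$alpha_mL_min2
}

#' Build the injection schedule for a campaign
#'
#' Enumerates every scheduled HPLC injection over the full factorial of
#' equivalents and temperature levels, computes each sample's residence time
#' by inverting the sweep integral, and attaches the inlet composition.
#'
#' @param design A [campaign_design()].
#' @return Tibble with one row per injection: `ramp_id`, `equivalents`,
#'   `temp_C`, `t_min`, `Q_total_mL_min` (pumped flow at the sampling
#'   instant), `beta`, `tau_res_min`, `C1_0_M`, `C2_0_M`.
#' @examples
#' nrow(injection_schedule(campaign_design())) # 72
#' @export
injection_schedule <- function(design) {
  duration <- ramp_duration_min(design)
  t_grid <- seq(0, duration, by = design$injection_interval_min)
  levels <- tidyr::expand_grid(
    equivalents = design$equivalents,
    temp_C = design$temperatures_C
  )
  levels$ramp_id <- seq_len(nrow(levels))
  purrr::pmap_dfr(levels, function(equivalents, temp_C, ramp_id) {
    beta <- thermal_expansion_factor(design$thermal, temp_C)
    tau <- residence_time(design$geometry, design$Q_start_mL_min,
      design$alpha_mL_min2, t_min = t_grid, beta = beta,
      hold_min = design$hold_min)
    tibble::tibble(
      ramp_id = ramp_id,
      equivalents = equivalents,
      temp_C = temp_C,
      t_min = t_grid,
      Q_total_mL_min = design$Q_start_mL_min - design$alpha_mL_min2 * t_grid,
      beta = beta,
      tau_res_min = tau,
      C1_0_M = design$C1_0_M,
      C2_0_M = design$C1_0_M * equivalents
    )
  })
}
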