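#' Arrhenius parameters at a reference temperature
#'
#' Rate constants are parameterized by their value `k_ref` at a reference
#' temperature `T_ref` rather than by a pre-exponential factor:
#' \deqn{k(T) = k_{ref} \exp\left[-\frac{E_a}{R}\left(\frac{1}{T} -
#'   \frac{1}{T_{ref}}\right)\right]}
#' This reparameterization keeps `k_ref` and `Ea` nearly uncorrelated when both
#' are estimated from data spanning a temperature window around `T_ref`, and it
#' makes `k_ref` directly comparable with rate constants reported at the
#' reference temperature.
#'
#' @param k_ref Rate constant at `T_ref` (M^-1 s^-1 for second-order steps,
#'   s^-1 for first-order steps). Must be positive.
#' @param Ea Activation energy in J mol^-1 (non-negative).
#' @param T_ref Reference temperature in K (default 363.15 K, i.e. 90 degC).
#' @return An object of class `arrhenius_params`.
#' @examples
#' p <- arrhenius_params(k_ref = 0.579, Ea = 33300)
#' arrhenius_k(p, T = 363.15) # returns k_ref exactly
#' arrhenius_k(p, T = 393.15)
#' @export
arrhenius_params <- function(k_ref, Ea, T_ref = 363.15) {
  check_number(k_ref, "k_ref", lower = .Machine$double.xmin)
  check_number(Ea, "Ea", lower = 0)
  check_number(T_ref, "T_ref", lower = .Machine$double.xmin)
  if (k_ref <= 0) abort_parameter("`k_ref` must be > 0.")
  structure(list(k_ref = k_ref, Ea = Ea, T_ref = T_ref),
    class = "arrhenius_params")
}

#' Evaluate an Arrhenius rate constant at a temperature
#'
#' @param params An [arrhenius_params()] object (or a list with fields
#'   `k_ref`, `Ea`, `T_ref`).
#' @param T Absolute temperature(s) in K; must be positive.
#' @return Rate constant(s) at `T`, same units as `k_ref`. Vectorized over `T`.
#' @export
arrhenius_k <- function(params, T) {
  if (any(!is.finite(T)) || any(T <= 0)) {
    abort_parameter("Temperature `T` must be positive and finite (kelvin).")
  }
  if (!is.numeric(params$k_ref) || params$k_ref <= 0) {
    abort_parameter("`params$k_ref` must be > 0.")
  }
  params$k_ref * exp(-(params$Ea / GAS_CONSTANT) * (1 / T - 1 / params$T_ref))
}
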