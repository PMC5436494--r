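#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a kinetic fit
#'
#' One row per estimated parameter with estimate, standard error and 95 %
#' confidence bounds on the natural scale (rate constants in M^-1 s^-1 at the
#' reference temperature, activation energies in J mol^-1).
#'
#' @param x A [fit_kinetics()] result.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std_error`,
#'   `conf_low`, `conf_high`, `unit`.
#' @export
tidy.kinetic_fit <- function(x, ...) x$estimates

#' One-row fit summary
#'
#' @param x A [fit_kinetics()] result.
#' @param ... Unused.
#' @return Tibble with `r_squared`, `sse`, `n_obs`, `n_par`, `dof`,
#'   `iterations`, `converged`.
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(
    r_squared = x$r_squared, sse = x$sse, n_obs = x$n_obs, n_par = x$n_par,
    dof = x$dof, iterations = x$convergence$iterations,
    converged = x$convergence$info %in% 1:4
  )
}

#' Measured vs fitted concentrations, one row per record x species
#'
#' @param x A [fit_kinetics()] result.
#' @param ... Unused.
#' @return The fit's sample table joined with long-format `species`,
#'   `measured`, `fitted` and `resid` columns.
#' @export
augment.kinetic_fit <- function(x, ...) {
  meta <- dplyr::mutate(x$table, row = dplyr::row_number())
  dplyr::left_join(x$fitted, meta, by = "row") |>
    dplyr::mutate(resid = .data$measured - .data$fitted)
}
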