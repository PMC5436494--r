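#' Plot a campaign's concentration-residence time profiles
#'
#' Points are the (possibly noisy) sampled concentrations against residence
#' time, faceted by ramp (equivalents x temperature).
#'
#' @param table A sample table from [run_campaign()].
#' @param species_cols Concentration columns to plot.
#' @return A ggplot object.
#' @export
plot_campaign <- function(table, species_cols = grep("^C[0-9]+_M$", names(table), value = TRUE)) {
  long <- tidyr::pivot_longer(table, dplyr::all_of(species_cols),
    names_to = "species", values_to = "conc_M")
  ggplot2::ggplot(long, ggplot2::aes(.data$tau_res_min, .data$conc_M,
    colour = .data$species)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::facet_grid(ggplot2::vars(.data$equivalents), ggplot2::vars(.data$temp_C),
      labeller = ggplot2::label_both) +
    ggplot2::labs(x = "residence time (min)", y = "concentration (M)",
      colour = NULL) +
    ggplot2::theme_bw()
}

#' Overlay fitted model curves on the campaign data
#'
#' @param object A [fit_kinetics()] result.
#' @param n_tau Number of residence-time points per fitted curve.
#' @param ... Unused.
#' @return A ggplot object: points = data, lines = fitted model.
#' @export
autoplot.kinetic_fit <- function(object, n_tau = 50, ...) {
  tbl <- object$table
  ids <- object$scheme$species$id
  res_ids <- unique(object$fitted$species)
  cols <- species_columns(object$scheme)[match(res_ids, ids)]
  curves <- dplyr::group_by(tbl, .data$ramp_id, .data$equivalents, .data$temp_C) |>
    dplyr::reframe(tau_res_min = seq(min(.data$tau_res_min), max(.data$tau_res_min),
      length.out = n_tau), C1_0_M = .data$C1_0_M[1], C2_0_M = .data$C2_0_M[1])
  pred <- simulate_at_conditions(object$scheme, curves)
  curves <- dplyr::bind_cols(curves, pred)
  data_long <- tidyr::pivot_longer(tbl, dplyr::all_of(cols),
    names_to = "column", values_to = "conc_M")
  pred_long <- tidyr::pivot_longer(curves, dplyr::all_of(cols),
    names_to = "column", values_to = "conc_M")
  ggplot2::ggplot(data_long, ggplot2::aes(.data$tau_res_min, .data$conc_M,
    colour = .data$column)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = pred_long) +
    ggplot2::facet_grid(ggplot2::vars(.data$equivalents), ggplot2::vars(.data$temp_C),
      labeller = ggplot2::label_both) +
    ggplot2::labs(x = "residence time (min)", y = "concentration (M)",
      colour = NULL, title = "Campaign data (points) and fitted model (lines)") +
    ggplot2::theme_bw()
}

#' Plot an F-curve and (optionally) its fitted step-response model
#'
#' @param f_curve Tibble with `time_s`, `F`.
#' @param fit Optional result of [estimate_kappa_from_f_curve()].
#' @param geom,u Needed with `fit` to draw the fitted model curve.
#' @return A ggplot object.
#' @export
plot_f_curve <- function(f_curve, fit = NULL, geom = NULL, u = NULL) {
  p <- ggplot2::ggplot(f_curve, ggplot2::aes(.data$time_s, .data$F)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "F (normalized step response)") +
    ggplot2::theme_bw()
  if (!is.null(fit) && !is.null(geom) && !is.null(u)) {
    tau <- geom$length_m / u
    grid <- seq(min(f_curve$time_s), max(f_curve$time_s), length.out = 200)
    model <- tibble::tibble(time_s = grid,
      F = f_curve_model(grid / tau, fit$Pe))
    p <- p + ggplot2::geom_line(data = model, colour = "red")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
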