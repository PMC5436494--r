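# YAML campaign configuration: load, validate, apply defaults, serialize.

config_defaults <- function() {
  list(
    reactor = list(volume_mL = 5, d_t_mm = 0.79, d_c_mm = NULL),
    thermal = list(alpha_v_per_K = 1.1e-3, T0_C = 25),
    fluid = list(density_kg_m3 = 789, viscosity_Pa_s = 1.07e-3, D_m_m2_s = 0.8e-9),
    ramp = list(Q_start_mL_min = 10, Q_end_mL_min = 1.5, alpha_mL_min2 = 0.836,
      injection_interval_min = 2, hold_min = 2),
    levels = list(equivalents = c(1.5, 4, 7), temperatures_C = c(30, 60, 90, 120)),
    stocks = list(C1_M = 0.5, C2_M = 2.0, C1_0_M = 0.1),
    scheme = list(name = "snar", nucleophile_stoich_factor = 1,
      aromatic_order = 1, nucleophile_order = 1,
      k_ref = c(0.579, 0.0270, 0.00865, 0.0163),
      Ea_J_mol = c(33300, 35300, 38900, 44800), T_ref_C = 90),
    noise = list(relative_sd = 0.02, absolute_sd_M = 1e-4),
    fit = list(weighting = "absolute", init = "two_stage", fit_Ea = TRUE),
    dispersion = list(kappa = 0.15, mask_threshold = 0.05, coefficient = "printed"),
    seed = 1L
  )
}

merge_config <- function(defaults, user, path = character(0)) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort_config(sprintf("Unknown config key(s)%s: %s.",
      if (length(path) > 0) sprintf(" under '%s'", paste(path, collapse = ".")) else "",
      paste(unknown, collapse = ", ")))
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) && is.list(user[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]], c(path, nm))
    } else {
      # wrap in list() so an explicit YAML null keeps the key present
      defaults[nm] <- list(user[[nm]])
    }
  }
  defaults
}

#' Load and validate a campaign configuration
#'
#' Reads a YAML configuration, applies defaults for absent keys, validates
#' units and ranges (naming the offending field), and computes a provenance
#' hash embedded in all pipeline outputs. The ramp rate may be given either
#' as `alpha_mL_min2` or explicitly as `alpha_mL_s2` (converted on load).
#'
#' @param path YAML file path, or `NULL` for the all-defaults configuration.
#' @return An object of class `campaign_config`: the normalized configuration
#'   list plus `$design` ([campaign_design()]), `$scheme`
#'   ([kinetic_scheme()]), `$noise` ([noise_model()]), `$hash`.
#' @export
load_campaign_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) abort_config(sprintf("Config file not found: %s", path))
    yaml::read_yaml(path)
  }
  if (!is.null(user$ramp$alpha_mL_s2)) {
    user$ramp$alpha_mL_min2 <- user$ramp$alpha_mL_s2 * 3600
    user$ramp$alpha_mL_s2 <- NULL
  }
  cfg <- merge_config(config_defaults(), user)
  validate_campaign_config(cfg)
}

validate_campaign_config <- function(cfg) {
  req_pos <- function(x, field) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
      abort_config(sprintf("Config field '%s' must be positive and finite (got %s).",
        field, paste(format(x), collapse = ", ")))
    }
  }
  req_pos(cfg$reactor$volume_mL, "reactor.volume_mL")
  req_pos(cfg$reactor$d_t_mm, "reactor.d_t_mm")
  req_pos(cfg$ramp$Q_start_mL_min, "ramp.Q_start_mL_min")
  req_pos(cfg$ramp$Q_end_mL_min, "ramp.Q_end_mL_min")
  req_pos(cfg$ramp$injection_interval_min, "ramp.injection_interval_min")
  req_pos(cfg$stocks$C1_M, "stocks.C1_M")
  req_pos(cfg$stocks$C2_M, "stocks.C2_M")
  req_pos(cfg$stocks$C1_0_M, "stocks.C1_0_M")
  req_pos(cfg$levels$equivalents, "levels.equivalents")
  req_pos(cfg$scheme$k_ref, "scheme.k_ref")
  if (cfg$ramp$alpha_mL_min2 < 0) abort_config("Config field 'ramp.alpha_mL_min2' must be >= 0.")
  if (!cfg$fit$weighting %in% c("absolute", "relative")) {
    abort_config("Config field 'fit.weighting' must be 'absolute' or 'relative'.")
  }

  geometry <- reactor_geometry(cfg$reactor$volume_mL, cfg$reactor$d_t_mm,
    cfg$reactor$d_c_mm %||% NA_real_)
  thermal <- thermal_expansion_model(cfg$thermal$alpha_v_per_K, cfg$thermal$T0_C)
  design <- campaign_design(
    geometry = geometry, thermal = thermal,
    Q_start_mL_min = cfg$ramp$Q_start_mL_min, Q_end_mL_min = cfg$ramp$Q_end_mL_min,
    alpha_mL_min2 = cfg$ramp$alpha_mL_min2,
    injection_interval_min = cfg$ramp$injection_interval_min,
    hold_min = cfg$ramp$hold_min,
    equivalents = cfg$levels$equivalents, temperatures_C = cfg$levels$temperatures_C,
    C1_0_M = cfg$stocks$C1_0_M, stock_C1_M = cfg$stocks$C1_M,
    stock_C2_M = cfg$stocks$C2_M)
  if (cfg$scheme$name != "snar") {
    abort_config("Only the built-in 'snar' scheme is available via config; construct custom schemes in code.")
  }
  scheme <- snar_scheme(k_ref = cfg$scheme$k_ref, Ea = cfg$scheme$Ea_J_mol,
    T_ref = celsius_to_kelvin(cfg$scheme$T_ref_C),
    nucleophile_stoich_factor = cfg$scheme$nucleophile_stoich_factor,
    aromatic_order = cfg$scheme$aromatic_order,
    nucleophile_order = cfg$scheme$nucleophile_order)
  noise <- noise_model(cfg$noise$relative_sd, cfg$noise$absolute_sd_M,
    seed = cfg$seed)
  fluid <- fluid_properties(cfg$fluid$density_kg_m3, cfg$fluid$viscosity_Pa_s,
    cfg$fluid$D_m_m2_s)
  structure(list(
    normalized = cfg, design = design, scheme = scheme, noise = noise,
    fluid = fluid, hash = config_hash(cfg)
  ), class = "campaign_config")
}

#' Serialize a campaign configuration to YAML
#'
#' Writes the fully normalized configuration (defaults applied), so loading
#' the written file and re-serializing reproduces it exactly.
#'
#' @param config A `campaign_config` from [load_campaign_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_campaign_config <- function(config, path) {
  yaml::write_yaml(config$normalized, path)
  invisible(path)
}
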