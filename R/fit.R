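# Global Arrhenius fitting of flow-ramp campaign data.

# Replace the Arrhenius parameters of a scheme (k_ref in M^-1 s^-1, Ea in
# J/mol, both length = number of steps).
set_scheme_params <- function(scheme, k_ref, Ea) {
  for (j in seq_along(scheme$steps)) {
    p <- scheme$steps[[j]]$params
    scheme$steps[[j]]$params <- arrhenius_params(k_ref[j], Ea[j], p$T_ref)
  }
  scheme
}

scheme_params <- function(scheme) {
  tibble::tibble(
    step = vapply(scheme$steps, function(s) s$label, character(1)),
    k_ref = vapply(scheme$steps, function(s) s$params$k_ref, numeric(1)),
    Ea = vapply(scheme$steps, function(s) s$params$Ea, numeric(1)),
    T_ref = vapply(scheme$steps, function(s) s$params$T_ref, numeric(1))
  )
}

#' Specification of a global kinetic fit
#'
#' @param k_init Initial guess for every step's rate constant at `T_ref`
#'   (M^-1 s^-1); scalar or length = number of steps.
#' @param Ea_init Initial guess for activation energies (J mol^-1).
#' @param k_bounds,Ea_bounds Length-2 bounds on the natural scale
#'   (M^-1 s^-1 and J mol^-1).
#' @param fit_Ea Logical: estimate activation energies (requires at least two
#'   temperature levels) or hold them at `Ea_init`.
#' @param residual_species Species ids entering the residual; default the
#'   aromatic (HPLC-visible) species.
#' @param weighting `"absolute"` (equal weights on concentrations, default) or
#'   `"relative"` (residuals scaled by `max(measured, rel_floor_M)`).
#' @param rel_floor_M Floor used by relative weighting (M).
#' @param init `"two_stage"` (default: first fit rate constants on the
#'   records at the reference temperature with Ea held fixed, then release
#'   everything -- the protocol used for ramp campaigns) or `"direct"`
#'   (start the global fit from `k_init`/`Ea_init` directly).
#' @param max_iter Maximum Levenberg-Marquardt iterations.
#' @param n_prescreen Size of the deterministic latin-hypercube pre-screen of
#'   the parameter space. The kinetic SSE landscape has saturation plateaus
#'   (fully converted profiles are insensitive to how much too large a rate
#'   constant is), so Levenberg-Marquardt is polished from the best
#'   `n_starts` of `n_prescreen` coarse candidates plus the supplied initial
#'   guess. Set to 0 to start from the initial guess only.
#' @param n_starts Number of pre-screen candidates polished by full LM runs.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(k_init = 0.1, Ea_init = 5e4,
                     k_bounds = c(1e-6, 1e3), Ea_bounds = c(0, 2e5),
                     fit_Ea = TRUE,
                     residual_species = NULL,
                     weighting = c("absolute", "relative"),
                     rel_floor_M = 1e-3,
                     init = c("two_stage", "direct"),
                     max_iter = 500, n_prescreen = 24, n_starts = 2) {
  weighting <- match.arg(weighting)
  init <- match.arg(init)
  if (any(k_init < k_bounds[1]) || any(k_init > k_bounds[2]) ||
      any(Ea_init < Ea_bounds[1]) || any(Ea_init > Ea_bounds[2])) {
    abort_config("Initial guesses must lie within the bounds.")
  }
  structure(list(k_init = k_init, Ea_init = Ea_init, k_bounds = k_bounds,
    Ea_bounds = Ea_bounds, fit_Ea = fit_Ea,
    residual_species = residual_species, weighting = weighting,
    rel_floor_M = rel_floor_M, init = init, max_iter = max_iter,
    n_prescreen = n_prescreen, n_starts = n_starts),
    class = "fit_spec")
}

# Internal: residual machinery shared by fitting and discrimination.
# theta = c(log k_ref (per step), Ea_kJ (per step, if fit_Ea)).
make_residual_fn <- function(table, scheme, spec) {
  ids <- scheme$species$id
  res_ids <- spec$residual_species %||% ids[scheme$species$role != "nucleophile"]
  cols <- species_columns(scheme)[match(res_ids, ids)]
  meas <- as.matrix(table[, cols, drop = FALSE])
  w <- if (spec$weighting == "relative") 1 / pmax(meas, spec$rel_floor_M) else 1
  nstep <- length(scheme$steps)
  function(theta) {
    k_ref <- exp(theta[seq_len(nstep)])
    Ea <- if (spec$fit_Ea) theta[nstep + seq_len(nstep)] * 1000 else rep(spec$Ea_init, length.out = nstep)
    sc <- set_scheme_params(scheme, k_ref, Ea)
    pred <- simulate_at_conditions(sc, table)
    as.numeric((as.matrix(pred[, cols, drop = FALSE]) - meas) * w)
  }
}

theta_from_spec <- function(spec, nstep) {
  k0 <- rep(spec$k_init, length.out = nstep)
  th <- log(k0)
  lower <- rep(log(spec$k_bounds[1]), nstep)
  upper <- rep(log(spec$k_bounds[2]), nstep)
  if (spec$fit_Ea) {
    th <- c(th, rep(spec$Ea_init, length.out = nstep) / 1000)
    lower <- c(lower, rep(spec$Ea_bounds[1] / 1000, nstep))
    upper <- c(upper, rep(spec$Ea_bounds[2] / 1000, nstep))
  }
  list(theta = th, lower = lower, upper = upper)
}

# Coarse global pre-screen of the SSE landscape. Returns the supplied start
# plus the best `n_starts - 1` points of a deterministic latin-hypercube
# sample over a physically plausible window (k_ref 1e-4..10 M^-1 s^-1,
# Ea 5..150 kJ/mol), ordered by coarse SSE.
prescreen_starts <- function(resid_fn, start, spec, nstep) {
  if (spec$n_prescreen < 1 || spec$n_starts < 2) return(list(start$theta))
  p <- length(start$theta)
  lo <- pmax(start$lower, c(rep(log(1e-4), nstep), rep(5, p - nstep)))
  hi <- pmin(start$upper, c(rep(log(10), nstep), rep(150, p - nstep)))
  grid <- with_local_seed(1, lhs::randomLHS(spec$n_prescreen, p))
  cand <- t(lo + t(grid) * (hi - lo))
  if (p > nstep) {
    # candidates varying only the activation energies around the supplied
    # rate constants: dense coverage of the subspace the two-stage protocol
    # actually needs to search
    ea_grid <- with_local_seed(2, lhs::randomLHS(spec$n_prescreen, p - nstep))
    ea_cand <- t(lo[-seq_len(nstep)] + t(ea_grid) * (hi - lo)[-seq_len(nstep)])
    cand <- rbind(cand,
      cbind(matrix(start$theta[seq_len(nstep)], nrow = nrow(ea_cand),
        ncol = nstep, byrow = TRUE), ea_cand))
  }
  cand <- rbind(start$theta, cand)
  sse <- apply(cand, 1, function(th) {
    r <- tryCatch(resid_fn(th), error = function(e) Inf)
    sum(r^2)
  })
  keep <- unique(c(1L, order(sse)[seq_len(min(spec$n_starts - 1L, nrow(cand)))]))
  lapply(keep, function(i) cand[i, ])
}

#' Globally fit Arrhenius kinetic parameters to a campaign sample table
#'
#' Fits all rate constants (and optionally activation energies)
#' simultaneously to every concentration record in the table by
#' Levenberg-Marquardt nonlinear least squares. Rate constants are optimized
#' in log space for positivity; the model is evaluated by integrating the
#' kinetic ODEs at each record's temperature, inlet composition and residence
#' time.
#'
#' @param table A sample table from [run_campaign()] or [read_sample_table()];
#'   must carry `temp_C`, `tau_res_min`, `C1_0_M`, `C2_0_M` and the measured
#'   `C*_M` columns.
#' @param scheme A [kinetic_scheme()] defining the motif being fitted (its
#'   stored parameters are ignored except for `T_ref`).
#' @param spec A [fit_spec()].
#' @return An object of class `kinetic_fit` with elements `estimates` (tidy
#'   parameter table with SEs and 95 % confidence half-widths), `vcov`
#'   (natural-scale covariance), `sse`, `r_squared`, `residuals`, `fitted`,
#'   `dof`, `convergence`, and the fitted `scheme`.
#' @seealso [tidy.kinetic_fit()], [glance.kinetic_fit()],
#'   [autoplot.kinetic_fit()], [rank_rate_orders()]
#' @export
fit_kinetics <- function(table, scheme = snar_scheme(), spec = fit_spec()) {
  required <- c("temp_C", "tau_res_min", "C1_0_M", "C2_0_M")
  missing <- setdiff(required, names(table))
  if (length(missing) > 0) {
    abort_data(sprintf("Sample table is missing columns: %s.", paste(missing, collapse = ", ")))
  }
  nstep <- length(scheme$steps)
  n_temp <- length(unique(table$temp_C))
  if (spec$fit_Ea && n_temp < 2) {
    rlang::warn(paste(
      "Only one temperature level present: activation energies are not",
      "identifiable and their uncertainties will be unbounded."),
      class = "flowramp_identifiability_warning")
  }
  if (spec$init == "two_stage" && spec$fit_Ea) {
    t_ref_c <- scheme$steps[[1]]$params$T_ref - 273.15
    iso <- table[abs(table$temp_C - t_ref_c) < 1e-6, , drop = FALSE]
    if (nrow(iso) > nstep) {
      spec1 <- spec
      spec1$fit_Ea <- FALSE
      spec1$init <- "direct"
      # the isothermal stage is cheap (small table, 4 parameters): spend more
      # of the budget there, where the saturation plateaus live
      spec1$n_prescreen <- max(spec$n_prescreen, 48)
      spec1$n_starts <- max(spec$n_starts, 4)
      stage1 <- fit_kinetics(iso, scheme, spec1)
      spec$k_init <- stage1$estimates$estimate[seq_len(nstep)]
      spec$k_init <- pmin(pmax(spec$k_init, spec$k_bounds[1]), spec$k_bounds[2])
    }
  }
  resid_fn <- make_residual_fn(table, scheme, spec)
  start <- theta_from_spec(spec, nstep)
  starts <- prescreen_starts(resid_fn, start, spec, nstep)
  ctrl <- minpack.lm::nls.lm.control(maxiter = spec$max_iter,
    ftol = 1e-12, ptol = 1e-12, gtol = 1e-10)
  fit <- NULL
  for (theta0 in starts) {
    cand <- minpack.lm::nls.lm(par = theta0, lower = start$lower,
      upper = start$upper, fn = resid_fn, control = ctrl)
    if (is.null(fit) || cand$deviance < fit$deviance) fit <- cand
  }
  if (fit$info == 0 || fit$info == 9) {
    abort_convergence(sprintf(
      "Levenberg-Marquardt failed to converge (info = %d: %s).",
      fit$info, fit$message))
  }
  build_fit_result(fit, table, scheme, spec)
}

build_fit_result <- function(fit, table, scheme, spec) {
  nstep <- length(scheme$steps)
  theta <- fit$par
  k_ref <- exp(theta[seq_len(nstep)])
  Ea <- if (spec$fit_Ea) theta[nstep + seq_len(nstep)] * 1000 else rep(spec$Ea_init, length.out = nstep)
  fitted_scheme <- set_scheme_params(scheme, k_ref, Ea)

  r <- fit$fvec
  sse <- sum(r^2)
  n <- length(r)
  p <- length(theta)
  dof <- n - p
  if (dof <= 0) abort_data("No residual degrees of freedom: more parameters than informative points.")

  jtj <- fit$hessian
  cond <- tryCatch(kappa(jtj, exact = TRUE), error = function(e) Inf)
  if (!is.finite(cond) || cond > 1e12) {
    rlang::warn(sprintf(
      "Ill-conditioned J'J at the optimum (condition number %.3g); parameter uncertainties are unreliable.",
      cond), class = "flowramp_identifiability_warning")
  }
  s2 <- sse / dof
  sv <- svd(jtj)
  null_dirs <- sv$d <= max(sv$d) * 1e-12
  cov_theta <- s2 * robust_inverse(jtj)
  if (any(null_dirs)) {
    # parameters loading on unidentifiable directions get infinite variance
    loading <- rowSums(abs(sv$v[, null_dirs, drop = FALSE]))
    diag(cov_theta)[loading > 1e-8] <- Inf
  }
  # delta method: k = exp(log k); Ea natural = 1000 * Ea_kJ
  grad <- c(k_ref, if (spec$fit_Ea) rep(1000, nstep))
  cov_nat <- cov_theta * outer(grad, grad)
  se <- sqrt(pmax(diag(cov_nat), 0))
  tq <- stats::qt(0.975, dof)

  at_bound <- theta <= theta_from_spec(spec, nstep)$lower + 1e-9 |
    theta >= theta_from_spec(spec, nstep)$upper - 1e-9
  if (any(at_bound)) {
    rlang::warn(
      "One or more parameter estimates sit at their bounds; the optimum is likely spurious.",
      class = "flowramp_boundary_warning")
  }

  step_labels <- vapply(scheme$steps, function(s) s$label, character(1))
  terms <- c(paste0("k_", step_labels), if (spec$fit_Ea) paste0("Ea_", step_labels))
  est <- c(k_ref, if (spec$fit_Ea) Ea)
  dimnames(cov_nat) <- list(terms, terms)
  estimates <- tibble::tibble(
    term = terms,
    estimate = est,
    std_error = se,
    conf_low = est - tq * se,
    conf_high = est + tq * se,
    unit = c(rep("M^-1 s^-1", nstep), if (spec$fit_Ea) rep("J mol^-1", nstep))
  )

  ids <- scheme$species$id
  res_ids <- spec$residual_species %||% ids[scheme$species$role != "nucleophile"]
  cols <- species_columns(scheme)[match(res_ids, ids)]
  meas <- as.matrix(table[, cols, drop = FALSE])
  pred <- as.matrix(simulate_at_conditions(fitted_scheme, table)[, cols, drop = FALSE])
  sse_conc <- sum((pred - meas)^2)
  sstot <- sum((meas - mean(meas))^2)
  r2 <- if (sstot > 0) 1 - sse_conc / sstot else
    abort_data("Total variance of the measured concentrations is zero; R^2 undefined.")

  fitted_long <- tibble::tibble(
    row = rep(seq_len(nrow(table)), times = length(cols)),
    species = rep(res_ids, each = nrow(table)),
    measured = as.numeric(meas),
    fitted = as.numeric(pred)
  )

  structure(list(
    estimates = estimates, vcov = cov_nat, sse = sse, sse_conc = sse_conc,
    r_squared = r2, residuals = as.numeric(meas - pred),
    fitted = fitted_long, dof = dof, n_obs = n, n_par = p,
    convergence = list(info = fit$info, message = fit$message,
      iterations = fit$niter, condition_number = cond),
    scheme = fitted_scheme, spec = spec, table = table,
    t_quantile = tq
  ), class = "kinetic_fit")
}

# Inverse that falls back to a pseudo-inverse for singular J'J.
robust_inverse <- function(m) {
  out <- tryCatch(solve(m), error = function(e) NULL)
  if (!is.null(out)) return(out)
  s <- svd(m)
  pos <- s$d > max(s$d) * 1e-12
  s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*% t(s$u[, pos, drop = FALSE])
}

#' Coefficient of determination of a kinetic fit
#'
#' `R^2 = 1 - SSE / SStot` where SSE sums squared concentration residuals
#' over all residual species at all records and SStot is taken about the
#' grand mean of all measured concentrations (documented convention).
#'
#' @param fit A [fit_kinetics()] result.
#' @return A single number `<= 1`.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "kinetic_fit"))
  fit$r_squared
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit>: %d parameters, %d observations, R^2 = %.5f\n",
    x$n_par, x$n_obs, x$r_squared))
  cat(format_fit_table(x), sep = "\n")
  invisible(x)
}

#' Human-readable parameter table
#'
#' Formats estimates the way kinetic studies report them: rate constants as
#' `k +/- SE` in 1e-2 M^-1 s^-1 at the reference temperature, activation
#' energies as `Ea +/- SE` in kJ mol^-1.
#'
#' @param fit A [fit_kinetics()] result.
#' @return Character vector of table lines.
#' @export
format_fit_table <- function(fit) {
  est <- fit$estimates
  kk <- est[grepl("^k_", est$term), ]
  ea <- est[grepl("^Ea_", est$term), ]
  t_ref <- fit$scheme$steps[[1]]$params$T_ref
  lines <- sprintf("  %-8s k = %7.3f +/- %6.3f (1e-2 M^-1 s^-1 at %.0f K)%s",
    sub("^k_", "", kk$term), 100 * kk$estimate, 100 * kk$std_error, t_ref,
    if (nrow(ea) > 0) sprintf("   Ea = %5.2f +/- %5.2f kJ/mol",
      ea$estimate / 1000, ea$std_error / 1000) else "")
  c(sprintf("  Rate constants at T_ref = %.2f K:", t_ref), lines)
}
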