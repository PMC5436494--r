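# Shared fixtures. Expensive objects (campaign fits, Monte-Carlo replicates)
# are computed lazily once per test run and cached.

# Reference kinetic parameters of the built-in SNAr system (k at 90 degC in
# M^-1 s^-1, Ea in J mol^-1).
REF_K <- c(0.579, 0.0270, 0.00865, 0.0163)
REF_EA <- c(33300, 35300, 38900, 44800)

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

noiseless_table <- function() {
  cached("noiseless_table",
    run_campaign(campaign_design(), snar_scheme(), noise = NULL))
}

noiseless_fit <- function() {
  cached("noiseless_fit",
    fit_kinetics(noiseless_table(), snar_scheme(), fit_spec()))
}

# 25 independent noisy campaigns at the default 2 % noise, each fitted
# globally; used for recovery-error and SE-calibration checks. The fits use
# the direct path without the global pre-screen: estimator statistics are the
# object here, and the default initial guess is inside the basin.
fast_spec <- function(...) fit_spec(init = "direct", n_prescreen = 0, ...)

noisy_fit_ensemble <- function(n = 25) {
  cached("noisy_fit_ensemble", {
    design <- campaign_design()
    lapply(seq_len(n), function(i) {
      tbl <- run_campaign(design, snar_scheme(), noise = noise_model(), seed = 1000 + i)
      fit_kinetics(tbl, snar_scheme(), fast_spec())
    })
  })
}

# Fixed-step classical Runge-Kutta reference trajectory (independent of the
# adaptive lsoda path used by simulate_profile).
rk4_reference <- function(scheme, conc0, T, tau_end = 120, dt = 1e-3) {
  rhs <- flowramp:::ode_rhs_factory(scheme, T)
  times <- seq(0, tau_end, by = dt)
  sol <- deSolve::rk4(y = conc0[scheme$species$id], times = times,
    func = rhs, parms = NULL)
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "tau_s"
  out
}

# Random but structurally valid SNAr parameter draw.
random_snar_scheme <- function() {
  snar_scheme(k_ref = stats::runif(4, 0.001, 1), Ea = stats::runif(4, 1e4, 8e4))
}
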