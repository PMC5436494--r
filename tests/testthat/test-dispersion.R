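test_that("dimensionless groups match direct arithmetic and their limits", {
  fl <- fluid_properties()
  geom <- reactor_geometry(d_c_mm = 30)
  g <- dimensionless_groups(geom, fl, u = 0.34)
  expect_equal(g$Re, 198, tolerance = 1e-3)
  expect_equal(g$Sc, 1695, tolerance = 1e-3)
  expect_equal(g$De, g$Re * sqrt(0.79 / 30))
  expect_equal(g$DeSc05, g$De * sqrt(g$Sc))
  # straight-tube limit: De -> 0 as the coil widens
  wide <- dimensionless_groups(reactor_geometry(d_c_mm = 1e9), fl, 0.34)
  expect_lt(wide$De, 1e-2)
  # Re and Sc are invariant under joint rescaling of rho and mu
  fl2 <- fluid_properties(789 * 3, 1.07e-3 * 3, 0.8e-9)
  g2 <- dimensionless_groups(geom, fl2, 0.34)
  expect_equal(g2$Re, g$Re)
  expect_equal(g2$Sc, g$Sc)
  expect_error(dimensionless_groups(reactor_geometry(), fl, 0.34),
    class = "flowramp_config_error")
})

test_that("Taylor-Aris dispersion obeys its structure and limits", {
  u <- 0.03; d <- 0.79e-3; Dm <- 0.8e-9
  expect_equal(taylor_aris_dispersion(u, d, Dm, kappa = 1),
    Dm + d^2 * u^2 / (192 * Dm))
  # linear in kappa (convective part)
  full <- taylor_aris_dispersion(u, d, Dm, 1) - Dm
  half <- taylor_aris_dispersion(u, d, Dm, 0.5) - Dm
  expect_equal(half, full / 2)
  expect_equal(taylor_aris_dispersion(0, d, Dm, 1), Dm)
  expect_error(taylor_aris_dispersion(u, d, Dm, kappa = 1.2),
    class = "flowramp_parameter_error")
  expect_error(taylor_aris_dispersion(u, d, Dm, kappa = 0),
    class = "flowramp_parameter_error")
})

test_that("the shipped kappa correlation interpolates sensibly", {
  corr <- kappa_correlation()
  expect_equal(kappa_from_correlation(65, corr), 0.31)
  expect_identical(kappa_from_correlation(0.1, corr), 1) # laminar limit
  x <- 10^seq(0.1, 3.2, length.out = 50)
  expect_true(all(diff(kappa_from_correlation(x, corr)) <= 1e-12))
  expect_warning(kappa_from_correlation(5000, corr), "tabulated range")
  expect_error(kappa_correlation(tibble::tibble(DeSc05 = numeric(0), kappa = numeric(0))),
    class = "flowramp_config_error")
  expect_error(kappa_correlation(tibble::tibble(DeSc05 = c(1, 2), kappa = c(0.5, 0.9))),
    class = "flowramp_config_error")
})

test_that("closed-vessel conversion recovers plug-flow and mixed-flow limits", {
  kt <- c(0.3, 1, 3)
  # dispersion -> 0: plug flow X = 1 - exp(-k tau)
  low <- conversion_with_dispersion(kt, 1, rep(1e-8, 3))
  expect_equal(low$X, 1 - exp(-kt), tolerance = 1e-6)
  # dispersion -> infinity: perfectly mixed X = k tau / (1 + k tau)
  high <- conversion_with_dispersion(kt, 1, rep(1e8, 3))
  expect_equal(high$X, kt / (1 + kt), tolerance = 1e-3)
  expect_equal(conversion_with_dispersion(1, 1, 1e8)$X, 0.5, tolerance = 1e-3)
  # small-dispersion series agrees to O(Pe^2)
  cw <- conversion_with_dispersion(1, 1, 0.01)
  expect_lt(abs(cw$X - cw$X_series), 1e-4)
  expect_true(cw$small_dispersion_valid)
  expect_false(conversion_with_dispersion(1, 1, 0.1)$small_dispersion_valid)
  expect_true(all(conversion_with_dispersion(runif(20, 0, 3), 1, runif(20, 0, 1))$X >= 0))
  expect_error(conversion_with_dispersion(1000, 1, 1e-4),
    class = "flowramp_numeric_error")
})

test_that("dispersion bias is negative, pinned to the printed evaluation, and monotone", {
  # printed constant: 1 mm tube, D_m = 0.8e-9 -> eps = -5 kappa k (i.e. -500 %)
  b <- suppressWarnings(rate_constant_bias(k = 1, d_t = 1e-3, D_m = 0.8e-9, kappa = 0.1))
  expect_equal(b$epsilon / (0.1 * 1), -5, tolerance = 1e-12)
  expect_equal(b$Da_r, 1 * (1e-3)^2 / 0.8e-9)
  # classical Taylor-Aris algebra variant
  b192 <- suppressWarnings(
    rate_constant_bias(1, 1e-3, 0.8e-9, 0.1, coefficient = "taylor_aris"))
  expect_equal(b192$epsilon / 0.1, -(1e-3)^2 / (192 * 0.8e-9), tolerance = 1e-12)
  # kappa = 0: no dispersion, no bias
  b0 <- rate_constant_bias(1, 1e-3, 0.8e-9, 0)
  expect_identical(b0$epsilon, 0)
  expect_identical(b0$k_obs, 1)
  # monotone in kappa, k and d_t; always <= 0
  suppressWarnings({
    eps_k <- rate_constant_bias(c(0.01, 0.1, 1), 1e-3, 0.8e-9, 0.1)$epsilon
    eps_kap <- rate_constant_bias(0.05, 1e-3, 0.8e-9, c(0.05, 0.15, 0.31))$epsilon
    eps_d <- vapply(c(0.5e-3, 1e-3, 2e-3), function(d)
      rate_constant_bias(0.05, d, 0.8e-9, 0.1)$epsilon, numeric(1))
  })
  expect_true(all(diff(eps_k) < 0) && all(diff(eps_kap) < 0) && all(diff(eps_d) < 0))
  expect_true(all(c(eps_k, eps_kap, eps_d) <= 0))
  expect_warning(rate_constant_bias(1, 1e-3, 0.8e-9, 1),
    class = "flowramp_expansion_warning")
})

test_that("pseudo-first-order lumping multiplies the nucleophile excess", {
  expect_equal(lumped_first_order(0.579, 0.027, 1), 0.606)
  expect_identical(lumped_first_order(0.579, 0.027, 0), 0)
  expect_equal(lumped_first_order(0.579, 0.027, 0.8),
    2 * lumped_first_order(0.579, 0.027, 0.4))
  expect_error(lumped_first_order(-1, 0, 1), class = "flowramp_parameter_error")
})
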