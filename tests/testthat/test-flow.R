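test_that("thermal expansion factor behaves as beta = 1 + alpha_v (T1 - T0)", {
  tm <- thermal_expansion_model(alpha_v = 1.1e-3, T0_C = 25)
  expect_identical(thermal_expansion_factor(tm, 25), 1)
  expect_equal(thermal_expansion_factor(tm, 120), 1.1045)
  expect_identical(thermal_expansion_factor(thermal_expansion_model(0, 25), 200), 1)
  expect_error(thermal_expansion_factor(tm, -100), class = "flowramp_parameter_error")
})

test_that("coil velocity follows u = beta (u_o - alpha t) / A", {
  geom <- reactor_geometry()
  expect_equal(velocity_at_time(geom, 10), 0.340, tolerance = 2e-3)
  # constant flow: velocity independent of time
  expect_equal(velocity_at_time(geom, 10, 0, t_min = 7), velocity_at_time(geom, 10))
  # linear in beta
  expect_equal(velocity_at_time(geom, 10, 0.836, 5, beta = 2.2),
    2.2 * velocity_at_time(geom, 10, 0.836, 5))
  expect_error(velocity_at_time(geom, 10, 0.836, t_min = 13),
    class = "flowramp_schedule_error")
})

test_that("residence time at steady flow is V/Q and the ramp quadratic matches it", {
  geom <- reactor_geometry() # 5 mL
  expect_equal(residence_time(geom, 10, 0, t_min = 0), 0.5, tolerance = 1e-12)
  # mid-ramp sample, frozen from bisection on the sweep integral
  expect_equal(residence_time(geom, 10, 0.836, t_min = 6), 0.9305817, tolerance = 1e-6)
  expect_equal(residence_time(geom, 10, 0.836, t_min = 6),
    residence_time(geom, 10, 0.836, t_min = 6, method = "numeric"),
    tolerance = 1e-9)
})

test_that("closed-form residence time equals numerical sweep inversion on random draws", {
  withr::with_seed(21, {
    for (i in 1:1000) {
      q0 <- runif(1, 2, 12)
      a <- runif(1, 0.05, 1)
      beta <- runif(1, 0.95, 1.15)
      t_max <- (q0 - 1) / a # keep Q(t) >= 1 mL/min
      t <- runif(1, 0, t_max)
      geom <- reactor_geometry(volume_mL = runif(1, 1, 6))
      tau_c <- residence_time(geom, q0, a, t, beta = beta)
      tau_n <- residence_time(geom, q0, a, t, beta = beta, method = "numeric")
      expect_lt(abs(tau_c - tau_n) * 60, 1e-6) # < 1e-6 s
    }
  })
})

test_that("residence time is continuous in alpha and monotone along a ramp", {
  geom <- reactor_geometry()
  expect_equal(residence_time(geom, 10, 1e-9, t_min = 0),
    residence_time(geom, 10, 0, t_min = 0), tolerance = 1e-9)
  tau <- residence_time(geom, 10, 0.836, t_min = seq(0, 10, by = 1))
  expect_true(all(diff(tau) > 0))
})

test_that("a too-short pre-ramp hold is reported as an unswept reactor", {
  geom <- reactor_geometry()
  expect_error(residence_time(geom, 10, 0.836, t_min = 0, hold_min = 0.2),
    class = "flowramp_schedule_error")
  expect_error(residence_time(geom, 10, 0.836, t_min = 0, hold_min = 0.2,
    method = "numeric"), class = "flowramp_schedule_error")
})

test_that("inlet concentrations follow flow-weighted dilution", {
  x <- inlet_concentrations(Q_P1 = 2, Q_P2 = 5, Q_P3 = 0, stock_C1_M = 0.5, stock_C2_M = 2)
  expect_equal(x$C2_0_M, 0)
  expect_equal(x$equivalents, 0)
  # equal stocks and equal substrate/nucleophile flows give 1 equivalent
  y <- inlet_concentrations(3, 1.23, 3, 0.7, 0.7)
  expect_equal(y$equivalents, 1)
})

test_that("pump fractions solved for target equivalents round-trip exactly", {
  fr <- pump_fractions(c(1.5, 4, 7), C1_0_M = 0.1, stock_C1_M = 0.5, stock_C2_M = 2)
  for (i in 1:3) {
    back <- inlet_concentrations(fr$f_P1[i], fr$f_P2[i], fr$f_P3[i], 0.5, 2)
    expect_equal(back$equivalents, c(1.5, 4, 7)[i], tolerance = 1e-12)
    expect_equal(back$C1_0_M, 0.1, tolerance = 1e-12)
  }
  expect_error(pump_fractions(4, 0, 0.5, 2), class = "flowramp_config_error")
  expect_error(pump_fractions(40, 0.1, 0.5, 2), class = "flowramp_config_error")
})

test_that("the default factorial schedule has 6 injections per ramp, 72 in total", {
  sched <- injection_schedule(campaign_design())
  expect_identical(nrow(sched), 72L)
  expect_identical(as.integer(table(sched$ramp_id)), rep(6L, 12))
  expect_identical(length(unique(paste(sched$equivalents, sched$temp_C))), 12L)
})

test_that("injection counts follow floor(duration / interval) + 1 per ramp", {
  # interval longer than the ramp: a single injection at onset
  d1 <- campaign_design(injection_interval_min = 20, equivalents = 4, temperatures_C = 90)
  expect_identical(nrow(injection_schedule(d1)), 1L)
  # halving the interval: 12 * (floor(duration / dt) + 1)
  d2 <- campaign_design(injection_interval_min = 1)
  duration <- (10 - 1.5) / 0.836
  expect_identical(nrow(injection_schedule(d2)), 12L * (as.integer(duration %/% 1) + 1L))
})

test_that("schedule generation is deterministic and invalid designs are rejected", {
  expect_identical(injection_schedule(campaign_design()), injection_schedule(campaign_design()))
  expect_error(campaign_design(injection_interval_min = 0), class = "flowramp_config_error")
  expect_error(campaign_design(Q_end_mL_min = -1), class = "flowramp_config_error")
})
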