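state0 <- function(c1 = 0.1, c2 = 0.4) {
  c(dfnb = c1, pyr = c2, ortho = 0, para = 0, bis = 0)
}

test_that("step rates follow mass-action kinetics of the motif", {
  sc <- snar_scheme()
  # no nucleophile -> every substitution stalls
  expect_equal(unname(reaction_rates(sc, state0(1, 0), 363.15)), rep(0, 4))
  # at unit concentrations the first two rates sum to k1 + k2
  r <- reaction_rates(sc, c(dfnb = 1, pyr = 1, ortho = 0, para = 0, bis = 0), 363.15)
  expect_equal(unname(r[1] + r[2]), 0.606, tolerance = 1e-12)
  # first order in nucleophile: doubling C2 doubles every rate
  s <- c(dfnb = 0.05, pyr = 0.2, ortho = 0.02, para = 0.01, bis = 0.005)
  s2 <- s; s2["pyr"] <- 2 * s["pyr"]
  expect_equal(unname(reaction_rates(sc, s2, 363.15)),
    unname(2 * reaction_rates(sc, s, 363.15)))
})

test_that("scheme validation catches structural errors", {
  sp <- dplyr::bind_rows(species("a", role = "substrate"), species("n", role = "nucleophile"))
  expect_error(kinetic_scheme(dplyr::bind_rows(sp, species("a")), list()),
    class = "flowramp_config_error")
  bad_step <- reaction_step("s", c(a = 1, n = 1), c(a = -1, ghost = 1, n = -1),
    arrhenius_params(1, 0))
  expect_error(kinetic_scheme(sp, list(bad_step)), "unknown species",
    class = "flowramp_config_error")
  # destroying an aromatic core without producing one is rejected
  sink_step <- reaction_step("s", c(a = 1, n = 1), c(a = -1, n = -1),
    arrhenius_params(1, 0))
  expect_error(kinetic_scheme(sp, list(sink_step)), "aromatic",
    class = "flowramp_config_error")
  expect_error(reaction_step("s", c(a = 0), c(a = -1), arrhenius_params(1, 0)),
    class = "flowramp_config_error")
  expect_error(reaction_rates(snar_scheme(), c(dfnb = 1, pyr = 1), 363.15),
    class = "flowramp_data_error")
})

test_that("tau = 0 returns the initial state exactly", {
  sc <- snar_scheme()
  tr <- simulate_profile(sc, state0(), 363.15, tau = 0)
  expect_equal(unname(unlist(tr[1, sc$species$id])), unname(state0()))
})

test_that("aromatic and nucleophile balances hold on random parameter draws", {
  withr::with_seed(11, {
    for (i in 1:10) {
      sc <- random_snar_scheme()
      tr <- simulate_profile(sc, state0(0.1, runif(1, 0.1, 0.7)),
        T = runif(1, 300, 400), tau = c(0, 10, 30, 60, 120))
      tot <- conserved_totals(sc, tr)
      expect_lt(max(abs(tot$aromatic_total - tot$aromatic_total[1])), 1e-9)
      expect_lt(max(abs(tot$nucleophile_total - tot$nucleophile_total[1])), 1e-9)
    }
  })
})

test_that("nucleophile balance respects the stoichiometry factor nu = 2", {
  sc <- snar_scheme(nucleophile_stoich_factor = 2)
  tr <- simulate_profile(sc, state0(0.1, 0.7), 363.15, tau = c(0, 20, 60))
  tot <- conserved_totals(sc, tr)
  expect_lt(max(abs(tot$nucleophile_total - 0.7)), 1e-9)
  # twice the amine is consumed relative to nu = 1 for the same substitutions
  made <- tr$ortho + tr$para + 2 * tr$bis
  expect_equal(0.7 - tr$pyr, 2 * made, tolerance = 1e-8)
})

test_that("substrate decays and bis-adduct accumulates monotonically", {
  tr <- simulate_profile(snar_scheme(), state0(0.1, 0.7), 393.15,
    tau = seq(0, 120, by = 5))
  expect_true(all(diff(tr$dfnb) <= 1e-9))
  expect_true(all(diff(tr$bis) >= -1e-9))
})

test_that("adaptive integration agrees with fixed-step RK4 on the reference system", {
  sc <- snar_scheme()
  grid <- seq(0, 120, by = 10)
  adaptive <- simulate_profile(sc, state0(), 363.15, tau = grid)
  reference <- rk4_reference(sc, state0(), 363.15, tau_end = 120, dt = 1e-3)
  ref_rows <- reference[match(grid, round(reference$tau_s, 9)), sc$species$id]
  expect_lt(max(abs(as.matrix(adaptive[, sc$species$id]) - as.matrix(ref_rows))), 1e-6)
})

test_that("pseudo-first-order limit is recovered at large nucleophile excess", {
  sc <- snar_scheme()
  c1 <- 0.005; c2 <- 0.5 # 100-fold excess
  k_psi <- (REF_K[1] + REF_K[2]) * c2
  tau_star <- 1 / k_psi # k * tau = 1
  tr <- simulate_profile(sc, c(dfnb = c1, pyr = c2, ortho = 0, para = 0, bis = 0),
    363.15, tau = c(0, tau_star))
  expect_equal(tr$dfnb[2] / c1, exp(-1), tolerance = 5e-3)
})
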