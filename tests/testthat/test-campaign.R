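test_that("a noiseless campaign reproduces per-record batch ODE solutions exactly", {
  tbl <- noiseless_table()
  expect_identical(nrow(tbl), 72L)
  sc <- snar_scheme()
  # independent route: one separate adaptive solve per record
  idx <- c(1, 18, 40, 72)
  for (i in idx) {
    conc0 <- c(dfnb = tbl$C1_0_M[i], pyr = tbl$C2_0_M[i], ortho = 0, para = 0, bis = 0)
    ref <- simulate_profile(sc, conc0, tbl$temp_C[i] + 273.15,
      tau = tbl$tau_res_min[i] * 60)
    got <- unlist(tbl[i, paste0("C", 1:5, "_M")])
    expect_equal(unname(got), unname(unlist(ref[1, sc$species$id])), tolerance = 1e-8)
  }
})

test_that("the default campaign spans the intended residence-time and condition ranges", {
  tbl <- noiseless_table()
  expect_gte(min(tbl$tau_res_min), 0.4)
  expect_lte(min(tbl$tau_res_min), 0.5)
  expect_gt(max(tbl$tau_res_min), 1.8)
  expect_identical(sort(unique(tbl$temp_C)), c(30, 60, 90, 120))
  expect_identical(sort(unique(tbl$equivalents)), c(1.5, 4, 7))
})

test_that("noiseless records satisfy the conservation invariants", {
  tbl <- noiseless_table()
  sc <- snar_scheme()
  traj <- tbl[, paste0("C", 1:5, "_M")]
  names(traj) <- sc$species$id
  tot <- conserved_totals(sc, traj)
  expect_lt(max(abs(tot$aromatic_total - tbl$C1_0_M)), 1e-9)
  expect_lt(max(abs(tot$nucleophile_total - tbl$C2_0_M)), 1e-9)
})

test_that("noise generation is seed-deterministic and respects its model", {
  des <- campaign_design()
  sc <- snar_scheme()
  t1 <- run_campaign(des, sc, noise = noise_model(), seed = 5)
  t2 <- run_campaign(des, sc, noise = noise_model(), seed = 5)
  expect_identical(t1, t2)
  t3 <- run_campaign(des, sc, noise = noise_model(), seed = 6)
  expect_false(identical(t1$C1_M, t3$C1_M))
  # zero sds: identity
  clean <- noiseless_table()
  expect_identical(apply_noise(clean, noise_model(0, 0), seed = 1), clean)
})

test_that("relative noise magnitude calibrates on replicate injections", {
  # 1e4 replicate perturbations of one clean record with C >> absolute floor
  base <- tibble::tibble(C1_M = rep(0.05, 1e4))
  noisy <- apply_noise(base, noise_model(relative_sd = 0.02, absolute_sd_M = 1e-6),
    seed = 99)
  cv <- sd(noisy$C1_M) / mean(noisy$C1_M)
  expect_equal(cv, 0.02, tolerance = 0.05)
  # unbiased within 3 standard errors (truncation negligible for C >> sd)
  se <- sd(noisy$C1_M) / sqrt(1e4)
  expect_lt(abs(mean(noisy$C1_M) - 0.05), 3 * se)
  # truncation at zero
  tiny <- apply_noise(tibble::tibble(C1_M = rep(1e-6, 1e3)),
    noise_model(0.02, 1e-4), seed = 3)
  expect_true(all(tiny$C1_M >= 0))
})

test_that("campaign metadata carries scheme id and config hash", {
  tbl <- noiseless_table()
  expect_identical(attr(tbl, "scheme_id"), "snar_a1n1_nu1")
  expect_match(attr(tbl, "config_hash"), "^[0-9a-f]{12}$")
  # same config -> same hash; different seed -> different hash
  t1 <- run_campaign(campaign_design(), snar_scheme(), noise = noise_model(), seed = 5)
  t2 <- run_campaign(campaign_design(), snar_scheme(), noise = noise_model(), seed = 5)
  t3 <- run_campaign(campaign_design(), snar_scheme(), noise = noise_model(), seed = 7)
  expect_identical(attr(t1, "config_hash"), attr(t2, "config_hash"))
  expect_false(identical(attr(t1, "config_hash"), attr(t3, "config_hash")))
})
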