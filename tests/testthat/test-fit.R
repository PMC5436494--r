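test_that("global fit recovers the generating parameters from noiseless data", {
  fit <- noiseless_fit()
  est <- fit$estimates$estimate
  expect_lt(max(abs(est[1:4] - REF_K) / REF_K), 1e-3)
  expect_lt(max(abs(est[5:8] - REF_EA) / REF_EA), 1e-3)
  # noiseless: uncertainties collapse
  expect_lt(max(fit$estimates$std_error / fit$estimates$estimate), 1e-6)
  expect_gte(fit$r_squared, 0.9995)
})

test_that("two-stage protocol (isothermal then global) reaches the same optimum", {
  fit2 <- fit_kinetics(noiseless_table(), snar_scheme(),
    fit_spec(init = "two_stage"))
  expect_equal(fit2$estimates$estimate, noiseless_fit()$estimates$estimate,
    tolerance = 1e-6)
})

test_that("activation energies are flagged unidentifiable at a single temperature", {
  tbl <- run_campaign(campaign_design(temperatures_C = 90), snar_scheme(), noise = NULL)
  classes <- character(0)
  withCallingHandlers(
    fit <- fit_kinetics(tbl, snar_scheme(), fit_spec()),
    warning = function(w) {
      classes <<- c(classes, class(w)[1])
      invokeRestart("muffleWarning")
    })
  expect_true("flowramp_identifiability_warning" %in% classes)
  ea <- fit$estimates[grepl("^Ea_", fit$estimates$term), ]
  expect_true(all(ea$std_error > ea$estimate))
  # the rate constants at T_ref remain well determined
  kk <- fit$estimates[grepl("^k_", fit$estimates$term), ]
  expect_lt(max(abs(kk$estimate - REF_K) / REF_K), 1e-3)
})

test_that("the optimum is insensitive to the starting point (multi-start)", {
  ref <- noiseless_fit()
  withr::with_seed(31, {
    for (i in 1:10) {
      spec <- fit_spec(k_init = 10^runif(4, -3, 0.5), Ea_init = runif(4, 1e4, 1e5))
      fit <- fit_kinetics(noiseless_table(), snar_scheme(), spec)
      expect_lt(abs(fit$sse - ref$sse), 1e-10)
      expect_equal(fit$estimates$estimate, ref$estimates$estimate, tolerance = 1e-4)
    }
  })
})

test_that("parameter recovery and SE calibration hold over replicate noisy campaigns", {
  fits <- noisy_fit_ensemble()
  k1 <- vapply(fits, function(f) f$estimates$estimate[1], numeric(1))
  ea1 <- vapply(fits, function(f) f$estimates$estimate[5], numeric(1))
  expect_lt(median(abs(k1 - REF_K[1]) / REF_K[1]), 0.05)
  expect_lt(median(abs(ea1 - REF_EA[1]) / REF_EA[1]), 0.05)
  # linearized SEs calibrate the sampling spread within a factor 1.5
  mean_se_k1 <- mean(vapply(fits, function(f) f$estimates$std_error[1], numeric(1)))
  expect_lt(sd(k1) / mean_se_k1, 1.5)
  expect_gt(sd(k1) / mean_se_k1, 1 / 1.5)
})

test_that("standard errors scale linearly with the noise level", {
  fits <- noisy_fit_ensemble()
  mean_se <- function(flist) {
    rowMeans(vapply(flist, function(f) f$estimates$std_error, numeric(8)))
  }
  base_se <- mean_se(fits[1:5])
  doubled <- lapply(1:5, function(i) {
    tbl <- run_campaign(campaign_design(), snar_scheme(),
      noise = noise_model(relative_sd = 0.04, absolute_sd_M = 2e-4), seed = 1000 + i)
    fit_kinetics(tbl, snar_scheme(), fast_spec())
  })
  ratio <- mean_se(doubled)[1:4] / base_se[1:4]
  expect_true(all(ratio > 1.4 & ratio < 2.8))
})

test_that("R-squared uses the grand-mean convention and is order-invariant", {
  fit <- noiseless_fit()
  expect_identical(goodness_of_fit(fit), fit$r_squared)
  withr::with_seed(8, {
    shuffled <- noiseless_table()[sample(72), ]
  })
  fit_shuffled <- fit_kinetics(shuffled, snar_scheme(), fast_spec())
  expect_equal(fit_shuffled$r_squared, fit$r_squared, tolerance = 1e-9)
})

test_that("fit input validation and tidiers behave", {
  expect_error(fit_kinetics(tibble::tibble(x = 1), snar_scheme()),
    class = "flowramp_data_error")
  expect_error(fit_spec(k_init = 1e5), class = "flowramp_config_error")
  fit <- noiseless_fit()
  td <- tidy(fit)
  expect_identical(td$term,
    c(paste0("k_step", 1:4), paste0("Ea_step", 1:4)))
  expect_true(all(td$conf_low <= td$estimate & td$estimate <= td$conf_high))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$converged)
  au <- augment(fit)
  expect_identical(nrow(au), 72L * 4L)
  expect_equal(au$measured - au$fitted, au$resid)
  # covariance symmetric PSD, R^2 <= 1
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8 * max(abs(ev))))
  expect_lte(fit$r_squared, 1)
})
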