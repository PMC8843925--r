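test_that("fits are deterministic under the seed", {
  mod <- calibration_conjugate_reduction(30, 100)
  f1 <- fit_model(mod, fc_short(seed = 7, iterations = 200))
  f2 <- fit_model(mod, fc_short(seed = 7, iterations = 200))
  expect_identical(as.matrix(f1$samples), as.matrix(f2$samples))
  f3 <- fit_model(mod, fc_short(seed = 8, iterations = 200))
  expect_false(identical(as.matrix(f1$samples), as.matrix(f3$samples)))
})

test_that("the conjugate reduction matches the Beta-Binomial closed form", {
  mod <- calibration_conjugate_reduction(30, 100)
  fit <- fit_model(mod, fc_short(seed = 1, iterations = 2000))
  qm <- mean(posterior_matrix(fit, "^q")[, 1])
  expect_equal(qm, 31 / 102, tolerance = 0.01)
})

test_that("draw dimensions honour the fit configuration", {
  mod <- calibration_conjugate_reduction(10, 40)
  cfg <- fit_config(chains = 3, adapt = 200, burnin = 100, iterations = 400,
                    thin = 2, seed = 2)
  fit <- fit_model(mod, cfg)
  expect_length(fit$samples, 3)
  expect_equal(nrow(fit$samples[[1]]), 200)  # iterations / thin
  expect_error(fit_config(chains = 1), "chains")
})

test_that("DIC identities hold for every fit", {
  d <- fixture_data(30, seed = 4)
  mod <- build_calibration_change_model(d, "nativeness", prior_form = "uniform")
  fit <- quiet_fit(mod, fc_short(seed = 3))
  for (scope in c("all", "calibration", "contemporary")) {
    dd <- compute_dic(fit, scope)
    expect_equal(dd$dic_paper - dd$Dhat, dd$pD, tolerance = 1e-9)
    expect_equal(dd$dic_paper, dd$Dbar, tolerance = 1e-9)
    expect_equal(dd$dic_standard, dd$Dhat + 2 * dd$pD, tolerance = 1e-9)
    expect_gt(dd$pD, 0)
  }
  # calibration + contemporary deviances partition the full deviance
  expect_equal(compute_dic(fit, "all")$Dbar,
               compute_dic(fit, "calibration")$Dbar +
                 compute_dic(fit, "contemporary")$Dbar, tolerance = 1e-6)
})

test_that("a zero-variance posterior has pD = 0 and DIC = Dhat", {
  dd <- dic_result(Dhat = 500, pD = 0)
  expect_equal(dd$dic_paper, 500)
  expect_equal(dd$dic_standard, 500)
  expect_equal(dd$Dbar, 500)
})

test_that("diagnostics flag divergent chains and pass identical ones", {
  set.seed(10)
  good <- coda::mcmc.list(coda::mcmc(cbind(theta = rnorm(500))),
                          coda::mcmc(cbind(theta = rnorm(500))))
  rep_good <- diagnostics_report(good)
  expect_lt(rep_good$rhat, 1.1)
  expect_false(rep_good$flagged)
  bad <- coda::mcmc.list(coda::mcmc(cbind(theta = rnorm(500))),
                         coda::mcmc(cbind(theta = rnorm(500, mean = 5))))
  rep_bad <- diagnostics_report(bad)
  expect_gt(rep_bad$rhat, 1.5)
  expect_true(rep_bad$flagged)
  empty <- coda::mcmc.list(coda::mcmc(matrix(numeric(0), 10, 0)),
                           coda::mcmc(matrix(numeric(0), 10, 0)))
  expect_equal(nrow(diagnostics_report(empty)), 0)
})

test_that("non-converged fits warn prominently", {
  d <- fixture_data(30, seed = 4)
  mod <- build_calibration_change_model(d, "nativeness", prior_form = "uniform")
  expect_warning(fit_model(mod, fit_config(chains = 2, adapt = 50, burnin = 0,
                                           iterations = 50, seed = 1)),
                 "convergence")
})

test_that("dic_table ranks models like a model-selection table", {
  d <- fixture_data(30, seed = 4)
  fits <- list(
    "Intercept (null)" = quiet_fit(
      build_calibration_change_model(d, "nativeness",
                                     include_attribute = FALSE,
                                     include_site_effect = FALSE),
      fc_short(seed = 5)),
    "Mostly native + eta" = quiet_fit(
      build_calibration_change_model(d, "nativeness", prior_form = "uniform"),
      fc_short(seed = 5))
  )
  tab <- dic_table(fits, scope = "calibration")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$DIC, tab$Dhat + tab$pD, tolerance = 1e-9)
  # the informative predictor beats the null on these data
  expect_equal(tab$model[1], "Mostly native + eta")
})
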