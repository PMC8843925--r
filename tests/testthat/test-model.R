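test_that("the joint graph shares one intercept and slope set across sub-models", {
  d <- fixture_data(30, seed = 1)
  mod <- build_calibration_change_model(d, "nativeness", prior_form = "uniform",
                                        site_covariates = "distance_upstream")
  # one declaration of a/b/c, used in both the calibration (q) and
  # prediction (lp) linear functions
  expect_equal(length(gregexpr("b\\[j\\] ~", mod$code)[[1]]), 1)
  expect_match(mod$code, "cloglog\\(q\\[k\\]\\) <- a \\+ inprod\\(b\\[\\], vc\\[k, \\]\\)")
  expect_match(mod$code, "lp\\[i\\] <- a \\+ inprod\\(b\\[\\], v\\[i, \\]\\)")
  # hits enter as counts from points, never as proportions
  expect_match(mod$code, "R\\[k\\] ~ dbin\\(q\\[k\\], m\\[k\\]\\)")
  expect_match(mod$code, "Y\\[i\\] ~ dbin\\(p\\[i\\], n\\[i\\]\\)")
  # change is additive on the link scale with the season covariate
  expect_match(mod$code, "w\\[i\\] \\+ gamma \\* Td\\[i\\]")
})

test_that("logit switch changes only the link operation", {
  d <- fixture_data(30, seed = 1)
  cll <- build_calibration_change_model(d, "nativeness", prior_form = "uniform")
  lgt <- build_calibration_change_model(d, "nativeness", prior_form = "uniform",
                                        link = "logit")
  expect_identical(gsub("logit", "cloglog", lgt$code), cll$code)
  expect_identical(lgt$data, cll$data)
})

test_that("density models use the Poisson family with an area offset", {
  d <- fixture_data(30, seed = 2, attributes = "recruit_density")
  mod <- build_calibration_change_model(d, "recruit_density",
                                        prior_form = "uniform")
  expect_match(mod$code, "R\\[k\\] ~ dpois\\(q\\[k\\] \\* area_cal\\[k\\]\\)")
  expect_match(mod$code, "Y\\[i\\] ~ dpois\\(p\\[i\\] \\* area\\[i\\]\\)")
  expect_false(grepl("gamma", mod$code))  # trees default season-insensitive
})

test_that("prior forms translate into the expected latent declarations", {
  d <- fixture_data(30, seed = 1)
  forms <- c(midpoint = NA, uniform = "dunif\\(L\\[i, j\\], U\\[i, j\\]\\)",
             normal = "dnorm\\(ref_mu\\[j\\], ref_tau\\[j\\]\\)$",
             truncated_normal = "dnorm\\(ref_mu\\[j\\], ref_tau\\[j\\]\\) T\\(")
  for (f in names(forms)) {
    mod <- build_calibration_change_model(d, "nativeness", prior_form = f)
    if (f == "midpoint") {
      expect_false(grepl("v\\[i, j\\] ~", mod$code))
      expect_true(is.matrix(mod$data$v))  # latents enter as data
    } else {
      expect_match(mod$code, paste0("v\\[i, j\\] ~ .*",
                                    sub("\\$$", "", forms[[f]])))
    }
  }
})

test_that("null model drops the latent predictor but keeps the structure", {
  d <- fixture_data(30, seed = 1)
  null <- build_calibration_change_model(d, "nativeness",
                                         include_attribute = FALSE)
  expect_false(grepl("inprod\\(b", null$code))
  expect_match(null$code, "eta\\[k\\]")
  expect_match(null$code, "w\\[i\\]")
  # the intercept-only model-selection null further drops the site effect
  bare <- build_calibration_change_model(d, "nativeness",
                                         include_attribute = FALSE,
                                         include_site_effect = FALSE)
  expect_false(grepl("eta\\[k\\]", bare$code))
})

test_that("second latent predictor (mostly weedy) can be included", {
  d <- fixture_data(30, seed = 1)
  mod <- build_calibration_change_model(d, "nativeness", prior_form = "uniform",
                                        include_weedy = TRUE)
  expect_equal(mod$meta$J, 2)
  expect_equal(ncol(mod$data$L), 2)
  expect_match(mod$code, "for \\(j in 1:2\\)")
})

test_that("percentage of historical value back-transforms correctly", {
  expect_equal(percentage_of_historical(0.2, 0.2), 100)
  expect_equal(percentage_of_historical(0.4, 0.2), 200)
  expect_equal(percentage_of_historical(c(10, 5), c(5, 10)), c(200, 50))
  expect_error(percentage_of_historical(0.4, 0), "undefined")
  expect_equal(percentage_of_historical(0.4, 0, epsilon = 0.01), 4000)
})

test_that("degenerate change gives identity: delta = 0 implies p = r", {
  # generator arithmetic: alpha = 0, gamma = 0 => contemporary == historical
  cfg <- generator_config(n_sites = 20, seed = 3,
                          params = list(nativeness = list(mu = 0, sigma = 0,
                                                          gamma = 0)))
  ts <- generate_true_states(generate_sites(cfg), cfg)
  natv <- ts[ts$attribute == "nativeness", ]
  expect_equal(natv$value_t2, natv$value_t1)
})

test_that("model specs serialise to JSON with their structure", {
  d <- fixture_data(30, seed = 1)
  mod <- build_calibration_change_model(d, "nativeness", prior_form = "uniform",
                                        site_covariates = "distance_upstream")
  js <- jsonlite::fromJSON(model_spec_json(mod))
  expect_equal(js$prior_form, "uniform")
  expect_equal(js$n_latent_predictors, 1)
  expect_equal(js$n_site_covariates, 1)
  expect_equal(js$n_sites, 30)
})

test_that("model construction validates its inputs", {
  d <- fixture_data(30, seed = 1)
  d$calibration <- NULL
  expect_error(build_calibration_change_model(d, "nativeness"),
               "calibration table")
  expect_error(build_calibration_change_model(fixture_data(30, seed = 1),
                                              "no_such_attribute"),
               "unknown attribute")
})
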