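test_that("generation is deterministic under seed and distinct across seeds", {
  c1 <- generator_config(n_sites = 30, seed = 7)
  a <- simulate_survey(c1)
  b <- simulate_survey(c1)
  expect_identical(a$sites, b$sites)
  expect_identical(a$historical, b$historical)
  expect_identical(a$contemporary, b$contemporary)
  expect_identical(a$calibration, b$calibration)
  d <- simulate_survey(generator_config(n_sites = 30, seed = 8))
  expect_false(identical(a$contemporary, d$contemporary))
})

test_that("site structure matches the study conditions", {
  cfg <- generator_config(n_sites = 180, calibration_fraction = 1 / 3, seed = 2)
  sites <- generate_sites(cfg)
  expect_equal(nrow(sites), 180)
  expect_equal(sum(sites$calibration), 60)
  expect_true(all(sites$area >= 0.5 & sites$area <= 19.9))
  expect_true(all(sites$distance_upstream >= 0 & sites$distance_upstream <= 200))
  # all five named management transitions occur
  cls <- assign_management_class(sites)
  expect_length(setdiff(unique(cls), "other"), 5)
  # point counts within the printed range
  d <- fixture_data(60, seed = 2)
  expect_true(all(d$contemporary$points >= 105 & d$contemporary$points <= 846))
})

test_that("generated data always pass validation", {
  for (seed in 1:3) {
    d <- simulate_survey(generator_config(
      n_sites = 25, seed = seed,
      attributes = c("nativeness", "recruit_density"), misclass_prob = 0.1))
    expect_silent(validate_survey_data(d))
  }
})

test_that("true state change arithmetic is exact on the link scale", {
  # zero-change null: value_t2 equals value_t1 at every site
  cfg0 <- generator_config(n_sites = 25, seed = 5,
                           params = list(nativeness = list(mu = 0, sigma = 0,
                                                           gamma = 0)))
  ts <- generate_true_states(generate_sites(cfg0), cfg0)
  natv <- ts[ts$attribute == "nativeness", ]
  expect_equal(natv$value_t2, natv$value_t1, tolerance = 1e-12)
  # log-link doubling: mu = ln 2 on a density doubles every site
  cfg2 <- generator_config(n_sites = 25, seed = 5,
                           attributes = "recruit_density",
                           params = list(recruit_density = list(
                             mu = log(2), sigma = 0, gamma = 0)))
  ts2 <- generate_true_states(generate_sites(cfg2), cfg2)
  expect_equal(ts2$value_t2, 2 * ts2$value_t1, tolerance = 1e-12)
  # generic invariant: link(value_t2) = link(value_t1) + alpha + season
  d <- fixture_data(30, seed = 3, attributes = "nativeness")
  tr <- d$truth
  expect_equal(link_transform(tr$value_t2, "cloglog"),
               link_transform(tr$value_t1, "cloglog") + tr$alpha +
                 tr$season_contrib, tolerance = 1e-9)
})

test_that("alpha draws follow the configured change distribution", {
  cfg <- generator_config(n_sites = 10000, seed = 11,
                          attributes = "nativeness",
                          params = list(nativeness = list(mu = 0.25,
                                                          sigma = 0.4)))
  ts <- generate_true_states(generate_sites(cfg), cfg)
  expect_equal(sd(ts$alpha), 0.4, tolerance = 0.03)
  expect_lt(abs(mean(ts$alpha) - 0.25), 0.02)
})

test_that("historical scoring thresholds and misclassification behave", {
  reg <- attribute_registry()
  # deterministic thresholding with no misclassification
  expect_identical(score_value(reg$medium_tree_density, 25), 1L)
  expect_identical(score_value(reg$medium_tree_density, 0), 0L)
  cfg <- generator_config(n_sites = 10000, seed = 13,
                          attributes = "recruit_density", misclass_prob = 0.2)
  sites <- generate_sites(cfg)
  ts <- generate_true_states(sites, cfg)
  hist <- generate_historical_survey(ts, cfg)
  flipped <- hist$score != ts$score_t1
  expect_equal(mean(flipped), 0.2, tolerance = 0.02)
  expect_true(all(abs(hist$score - ts$score_t1) <= 1))  # adjacent only
})

test_that("contemporary responses have the right sampling moments", {
  # binomial: points = 400, p = 0.5 -> mean 200, sd 10
  set.seed(1)
  hits <- rbinom(4000, 400, 0.5)
  expect_equal(mean(hits), 200, tolerance = 1)
  expect_equal(sd(hits), 10, tolerance = 0.5)
  # generated hits respect their own points
  d <- fixture_data(40, seed = 4)
  expect_true(all(d$contemporary$hits <= d$contemporary$points))
})

test_that("double-sampled scores agree with contemporary values when the observer is exact", {
  # identity calibration regression, no noise, no misclassification:
  # the contemporary value must lie inside the scored category
  cfg <- generator_config(
    n_sites = 40, seed = 9, attributes = "nativeness",
    params = list(nativeness = list(a = 0, b = 1, c = 0, sd_eta = 0)))
  d <- simulate_survey(cfg)
  cal <- d$calibration
  tr <- d$truth[match(cal$site_id, d$truth$site_id), ]
  for (i in seq_len(nrow(cal))) {
    b <- category_bounds(cfg$registry$nativeness, cal$mostly_native[i]) / 100
    expect_gte(tr$value_t2[i], b[1] - 1e-9)
    expect_lte(tr$value_t2[i], b[2] + 1e-9)
  }
})

test_that("calibration pairs cover exactly the flagged sites", {
  d <- fixture_data(60, seed = 6)
  flagged <- d$sites$site_id[d$sites$calibration]
  expect_setequal(d$calibration$site_id, flagged)
  expect_true(all(abs(d$calibration$offset_days) <= 14))
})
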