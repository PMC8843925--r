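test_that("k-fold splits are disjoint, covering and near-equal", {
  ids <- sprintf("S%02d", 1:60)
  f <- kfold_split(ids, 10, seed = 3)
  expect_equal(sort(unique(unname(f))), 1:10)
  expect_true(all(table(f) == 6))
  expect_setequal(names(f), ids)
  expect_identical(f, kfold_split(ids, 10, seed = 3))
  # uneven n: fold sizes differ by at most one
  f2 <- kfold_split(1:13, 4, seed = 1)
  expect_lte(diff(range(table(f2))), 1)
  expect_error(kfold_split(1:3, 5), "exceeds")
  expect_error(kfold_split(1:3, 1), ">= 2")
})

test_that("pearson_with_ci reproduces the Fisher-z closed form", {
  p <- pearson_with_ci(c(1, 2, 3, 4, 5), c(1, 2, 3, 5, 4))
  expect_equal(p$r, 0.9, tolerance = 1e-12)
  expect_equal(p$ci, c(0.0861019, 0.9934375), tolerance = 1e-6)
  # agreement with the standard implementation across random inputs
  set.seed(20)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1)); y <- 0.5 * x + rnorm(length(x))
    ours <- pearson_with_ci(x, y)
    ref <- cor.test(x, y)
    expect_equal(ours$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$ci, as.numeric(ref$conf.int), tolerance = 1e-6)
  }
  expect_equal(pearson_with_ci(1:5, 1:5)$r, 1)
  expect_equal(pearson_with_ci(1:5, -(1:5))$r, -1)
  expect_error(pearson_with_ci(1:3, 1:3), "4")
  expect_error(pearson_with_ci(rep(1, 6), 1:6), "constant")
})

test_that("cross-validation pools held-out predictions over all units", {
  d <- fixture_data(36, seed = 10)
  cv <- crossvalidate(d, "nativeness", method = "calibration",
                      prior_form = "uniform", k = 4,
                      config = fc_short(seed = 11, iterations = 400),
                      rhat_exclude = Inf)
  held <- unique(d$calibration$site_id)
  expect_setequal(cv$predictions$site_id, held)
  expect_equal(length(unique(cv$predictions$fold)), 4)
  expect_true(all(cv$predictions$predicted >= 0 & cv$predictions$predicted <= 1))
  expect_true(cv$r >= -1 && cv$r <= 1)
  expect_true(cv$ci[1] <= cv$r && cv$r <= cv$ci[2])
})

test_that("change summaries nest intervals and respect grouping", {
  d <- fixture_data(30, seed = 12)
  mod <- build_calibration_change_model(d, "nativeness", prior_form = "uniform")
  fit <- quiet_fit(mod, fc_short(seed = 13))
  cs <- summarize_change(fit, data = d, group_by = "management")
  expect_equal(nrow(cs$sites), 30)
  # 50% intervals nested within 95% intervals
  expect_true(all(cs$sites$q25 >= cs$sites$q2.5 - 1e-9))
  expect_true(all(cs$sites$q75 <= cs$sites$q97.5 + 1e-9))
  expect_true(cs$grand$q25 >= cs$grand$q2.5 && cs$grand$q75 <= cs$grand$q97.5)
  # groups cover the management classes present in the data
  cls <- assign_management_class(d$sites)
  expect_setequal(cs$groups$class, unique(cls))
  expect_equal(sum(cs$groups$n_sites), 30)
  # a single-site group's mean equals that site's mean
  singles <- cs$groups[cs$groups$n_sites == 1, ]
  if (nrow(singles)) {
    g <- singles$class[1]
    sid <- d$sites$site_id[cls == g]
    expect_equal(singles$mean[singles$class == g],
                 cs$sites$mean[cs$sites$site_id == sid])
  }
})

test_that("midpoint priors give zero-width historical intervals, spread priors do not", {
  d <- fixture_data(25, seed = 14, attributes = "recruit_density")
  cfg <- fc_short(seed = 15, iterations = 300)
  for (form in c("midpoint", "uniform")) {
    mod <- build_noncalibration_model(d, "recruit_density", prior_form = form)
    fit <- quiet_fit(mod, cfg)
    m <- as.matrix(fit$samples)
    if (form == "midpoint") {
      expect_false(any(grepl("^v\\[", colnames(m))))  # latents are constants
    } else {
      vsd <- apply(m[, grep("^v\\[", colnames(m))], 2, sd)
      expect_true(all(vsd > 0))
    }
  }
})

test_that("a small recovery experiment reports coverage, bias and rmse", {
  gc <- generator_config(n_sites = 40, seed = 500, mode = "from_model",
                         attributes = "nativeness")
  rec <- recovery_experiment(gc, replicates = 2,
                             fit_cfg = fc_short(seed = 16, iterations = 400))
  expect_setequal(rec$summary$parameter, c("a", "b", "c", "mu", "gamma"))
  expect_true(all(rec$summary$coverage >= 0 & rec$summary$coverage <= 1))
  expect_true(all(is.finite(rec$summary$rmse)))
  expect_equal(nrow(rec$per_replicate), 10)  # 5 parameters x 2 replicates
  # byte-identical on rerun with the same seeds
  rec2 <- recovery_experiment(gc, replicates = 2,
                              fit_cfg = fc_short(seed = 16, iterations = 400))
  expect_identical(rec$per_replicate, rec2$per_replicate)
})
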