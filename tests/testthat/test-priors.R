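reg <- attribute_registry()

test_that("midpoint values come from the printed category bounds", {
  expect_equal(midpoint_value(1, reg$medium_tree_density), 20)
  expect_equal(midpoint_value(0, reg$medium_tree_density), 0)
  expect_equal(midpoint_value(2, reg$medium_tree_density), 220)  # (40+400)/2
  # a midpoint prior is a point mass: zero-width support, identical draws
  mp <- midpoint_prior(1, reg$medium_tree_density)
  expect_equal(diff(mp$support), 0)
  expect_equal(sample_prior(mp, 5, seed = 1), rep(log(20), 5))
})

test_that("uniform priors span the scored category, with optional overlap", {
  up <- uniform_prior(1, reg$recruit_density)
  expect_equal(exp(up$support), c(0.05, 50), tolerance = 1e-10)
  # overlap widens each end by the fraction of the range, clipped below at 0
  ov <- uniform_prior(1, reg$medium_tree_density, overlap = 0.1)
  expect_equal(exp(ov$support[2]), 44, tolerance = 1e-10)
  expect_equal(exp(ov$support[1]), 0.05, tolerance = 1e-10)  # floored
  # composition scores: the window is the half-resolution band, clipped
  nat <- reg$nativeness
  expect_equal(inverse_link(uniform_prior(40, nat)$support, "cloglog"),
               c(0.375, 0.425), tolerance = 1e-10)
  expect_equal(inverse_link(uniform_prior(0, nat)$support[1], "cloglog"),
               5e-4, tolerance = 1e-10)
})

test_that("normal prior moments are the reference moments on the link scale", {
  ref <- exp(c(-1, 0, 1))  # log-transformed reference = (-1, 0, 1)
  np <- normal_prior(ref, reg$recruit_density)
  expect_equal(np$location, 0, tolerance = 1e-12)
  expect_equal(np$spread, 1, tolerance = 1e-12)  # sample SD
  expect_error(normal_prior(rep(2, 5), reg$recruit_density), "distinct")
})

test_that("all prior draws honour the declared support", {
  ref <- rgamma(50, 2, scale = 20)
  for (score in 0:2) {
    for (maker in list(
      function(s) uniform_prior(s, reg$recruit_density),
      function(s) truncated_normal_prior(s, ref, reg$recruit_density),
      function(s) midpoint_prior(s, reg$recruit_density)
    )) {
      pr <- maker(score)
      x <- sample_prior(pr, 2000, seed = score + 1)
      expect_true(all(x >= pr$support[1] - 1e-12 & x <= pr$support[2] + 1e-12))
    }
  }
  expect_identical(sample_prior(uniform_prior(1, reg$recruit_density), 100, seed = 3),
                   sample_prior(uniform_prior(1, reg$recruit_density), 100, seed = 3))
})

test_that("uniform draws are flat over the category range", {
  pr <- uniform_prior(1, reg$medium_tree_density)
  x <- sample_prior(pr, 1e4, seed = 2)
  ks <- suppressWarnings(ks.test(x, "punif", pr$support[1], pr$support[2]))
  expect_gt(ks$p.value, 0.001)
})

test_that("truncated normal sampling matches the closed-form mean", {
  ref <- rgamma(200, 2, scale = 25)
  pr <- truncated_normal_prior(1, ref, reg$recruit_density)
  x <- sample_prior(pr, 1e5, seed = 4)
  expect_equal(mean(x), truncated_normal_mean(pr),
               tolerance = 0.01 * abs(truncated_normal_mean(pr)))
  # truncation to the whole support reproduces the untruncated normal
  np <- normal_prior(ref, reg$recruit_density)
  wide <- prior_spec("truncated_normal",
                     support = np$location + c(-20, 20) * np$spread,
                     location = np$location, spread = np$spread, link = "log")
  xs <- sample_prior(wide, 1e4, seed = 5)
  xn <- sample_prior(np, 1e4, seed = 5)
  expect_gt(suppressWarnings(ks.test(xs, xn))$p.value, 0.001)
})

test_that("degenerate configurations error or warn as specified", {
  naked <- attribute_spec("medium_tree_density", "density", "poisson_log",
                          categories = list(category_def("None", 0, 0, 0),
                                            category_def("Some", 0, 40, 1),
                                            category_def("Much", 40, Inf, 2)),
                          open_end_cap = 400)
  expect_error(attribute_spec("x", "density", "poisson_log",
                              categories = naked$categories), "open_end_cap")
  # reference normal with no mass in the category triggers a warning
  expect_warning(
    truncated_normal_prior(0, rep(c(380, 400, 420), 5), reg$recruit_density),
    "no mass")
})
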