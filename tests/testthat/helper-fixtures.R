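# shared fixtures: small simulated datasets, cached per test run
.fixture_cache <- new.env(parent = emptyenv())

fixture_data <- function(n_sites = 40, seed = 1, attributes = "nativeness",
                         mode = "observer", ...) {
  key <- paste(n_sites, seed, paste(attributes, collapse = "+"), mode, ...)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_survey(generator_config(
      n_sites = n_sites, seed = seed, attributes = attributes, mode = mode, ...))
  }
  .fixture_cache[[key]]
}

# short MCMC settings for unit tests (not production defaults)
fc_short <- function(seed = 42, chains = 2, adapt = 300, burnin = 300,
                     iterations = 500) {
  fit_config(chains = chains, adapt = adapt, burnin = burnin,
             iterations = iterations, seed = seed)
}

quiet_fit <- function(model, config) suppressWarnings(fit_model(model, config))

# a tiny hand-built three-site dataset for I/O tests
tiny_dataset <- function() {
  sites <- data.frame(
    site_id = c("A", "B", "C"),
    distance_upstream = c(10, 50, 120), creek = "broken",
    area = c(1.5, 3, 7), road = c(0, 1, 0), cropping = c(0, 0, 1),
    grazing = c(1, 1, 0), water = c(0, 1, 1),
    days_offset = c(-5, 12, 30),
    licence_t1 = c(1, 0, 1), fence_t1 = c(1, 1, 0),
    licence_t2 = c(0, 0, 1), fence_t2 = c(1, 1, 1)
  )
  historical <- data.frame(
    site_id = c("A", "B", "C"), attribute = "nativeness",
    score = NA_integer_,
    mostly_native = c(40, 70, 10), mostly_weedy = c(35, 20, 60),
    fifty_fifty = c(15, 5, 20), bare = c(10, 5, 10)
  )
  contemporary <- data.frame(
    site_id = c("A", "B", "C"), attribute = "nativeness",
    hits = c(120, 300, 40), points = c(400, 500, 200),
    count = NA_integer_, sampled_area = NA_real_
  )
  calibration <- data.frame(
    site_id = "B", attribute = "nativeness", score = NA_integer_,
    mostly_native = 65, mostly_weedy = 25, fifty_fifty = 5, bare = 5,
    hits = 300, points = 500, count = NA_integer_, sampled_area = NA_real_,
    offset_days = 3
  )
  survey_data(sites, historical, contemporary, calibration)
}
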