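#' Configuration for the synthetic survey generator
#'
#' The generator emulates the statistical structure of a two-period
#' riparian vegetation study: ~180 contemporary sites strung along ~200 km of
#' creek, one third double-sampled, point-intercept counts per site in the
#' observed range (105-846 points), belt-quadrat tree counts with sampled
#' areas from a transect layout, and the five grazing-management transitions.
#'
#' Two generation modes are provided:
#' \describe{
#'   \item{`"observer"`}{(default) a physically-motivated chain: a perceived
#'     subjective state underlies each categorical score, the objective
#'     historical state follows the calibration regression, and at
#'     double-sampled sites the two methods measure the same contemporary
#'     state (the pair's quantitative record is the site's contemporary
#'     observation).}
#'   \item{`"from_model"`}{ancestral simulation from the joint model graph
#'     itself: given the scores, latent predictor values are drawn uniformly
#'     within the scored category on the link scale and all responses are
#'     simulated forward. This is the mode used by parameter-recovery and
#'     coverage experiments, where the estimator is checked against the
#'     model's own generative assumptions.}
#' }
#'
#' @param n_sites number of contemporary sites.
#' @param calibration_fraction fraction of sites double-sampled, in (0, 1].
#' @param seed integer seed; the seed fully determines the dataset.
#' @param mode `"observer"` or `"from_model"` (see above).
#' @param attributes which registry attributes to generate.
#' @param params named list (per attribute) of true model parameters:
#'   `a` (intercept), `b` (coefficient of the link-transformed subjective
#'   attribute), `c` (coefficient of the scaled site covariate), `sd_eta`
#'   (between-site SD of the method relationship, shared by the calibration
#'   and prediction deviations), `mu` and `sigma` (mean and SD of site-level
#'   change on the link scale), `gamma` (per-day season coefficient).
#' @param misclass_prob probability that a categorical score is flipped to an
#'   adjacent category (adjacent-category observer error).
#' @param points_range range of point-intercept points per site.
#' @param points_median median points per site (lognormal draw, clipped).
#' @param days_range range (days) of the day-of-year offset between surveys.
#' @param area_range site area range (ha).
#' @param distance_range distance-upstream span (km).
#' @param registry attribute registry; defaults to [attribute_registry()].
#' @param density_shape,density_scale Gamma parameters of nonzero historical
#'   subjective densities (stems/ha).
#' @param density_zero_prob probability a site's subjective density is 0.
#' @param beta_shape1,beta_shape2 Beta parameters of the subjective
#'   mostly-native fraction of vegetated cover.
#' @param p_floor floor applied to proportions before link transforms
#'   (edge scoring bins extend to this floor rather than 0 or 1).
#' @param d_floor floor (stems/ha) for densities before log transforms.
#' @param pulse_prob probability that a density site scored "None"
#'   historically receives an episodic recruitment pulse by the contemporary
#'   survey (e.g. mass germination after flooding). Such pulses are exactly
#'   the events a multiplicative change model cannot generate from a zero
#'   baseline; they are off by default and exist to probe how prior forms
#'   behave at score-zero sites.
#' @param pulse_density mean pulse size (stems/ha).
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_sites = 180,
                             calibration_fraction = 1 / 3,
                             seed = 1,
                             mode = c("observer", "from_model"),
                             attributes = c("nativeness", "recruit_density",
                                            "medium_tree_density"),
                             params = NULL,
                             misclass_prob = 0,
                             points_range = c(105, 846),
                             points_median = 382,
                             days_range = c(-60, 60),
                             area_range = c(0.5, 19.9),
                             distance_range = c(0, 200),
                             registry = attribute_registry(),
                             density_shape = 1.6,
                             density_scale = 28,
                             density_zero_prob = 0.15,
                             beta_shape1 = 2,
                             beta_shape2 = 2,
                             p_floor = 5e-4,
                             d_floor = 0.05,
                             pulse_prob = 0,
                             pulse_density = 25) {
  mode <- match.arg(mode)
  if (calibration_fraction <= 0 || calibration_fraction > 1) {
    stop("calibration_fraction must be in (0, 1]", call. = FALSE)
  }
  default_params <- list(
    nativeness = list(a = 0.2, b = 0.8, c = -0.3, sd_eta = 0.3,
                      mu = 0.1, sigma = 0.3, gamma = 0.003),
    recruit_density = list(a = 0.4, b = 0.9, c = 0.2, sd_eta = 0.3,
                           mu = 0, sigma = 0.25, gamma = 0),
    medium_tree_density = list(a = 0.4, b = 0.9, c = 0.1, sd_eta = 0.25,
                               mu = 0, sigma = 0.1, gamma = 0)
  )
  if (!is.null(params)) {
    for (nm in names(params)) {
      default_params[[nm]][names(params[[nm]])] <- params[[nm]]
    }
  }
  for (pp in default_params) {
    if (pp$sd_eta < 0 || pp$sigma < 0) stop("SDs must be >= 0", call. = FALSE)
  }
  structure(list(
    n_sites = n_sites, calibration_fraction = calibration_fraction,
    seed = as.integer(seed), mode = mode, attributes = attributes,
    params = default_params, misclass_prob = misclass_prob,
    points_range = points_range, points_median = points_median,
    days_range = days_range, area_range = area_range,
    distance_range = distance_range, registry = registry,
    density_shape = density_shape, density_scale = density_scale,
    density_zero_prob = density_zero_prob,
    beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
    p_floor = p_floor, d_floor = d_floor,
    pulse_prob = pulse_prob, pulse_density = pulse_density
  ), class = "generator_config")
}

# scaled site covariate used by the true regressions (distance upstream)
site_covariate <- function(sites) {
  d <- sites$distance_upstream
  (d - mean(d)) / (2 * stats::sd(d))
}

#' Generate site records
#'
#' Sites are spread over the configured distance span with areas, binary
#' site descriptors, management states covering all five named transitions
#' (for `n_sites >= 20`), day-of-year offsets between survey periods, and a
#' double-sampling flag for the calibration subset.
#'
#' @param config a [generator_config()].
#' @return data.frame of site records with a logical `calibration` column.
#' @export
generate_sites <- function(config) {
  set.seed(config$seed)
  n <- config$n_sites
  if (n < 2) stop("n_sites must be >= 2", call. = FALSE)
  tab <- management_class_table()
  cls <- sample(c(seq_len(nrow(tab)), 0), n, replace = TRUE,
                prob = c(0.22, 0.2, 0.16, 0.14, 0.2, 0.08))
  if (n >= 20) {
    for (j in seq_len(nrow(tab))) {          # guarantee each named transition
      if (!any(cls == j)) cls[sample(which(cls == 0 | duplicated(cls)), 1)] <- j
    }
  }
  mg <- matrix(0L, n, 4)
  named <- cls > 0
  mg[named, ] <- as.matrix(tab[cls[named], 1:4])
  # "other" sites: combinations outside the five named transitions
  mg[!named, ] <- cbind(0L, 0L, sample(0:1, sum(!named), TRUE), 0L)
  sites <- data.frame(
    site_id = sprintf("S%03d", seq_len(n)),
    distance_upstream = round(stats::runif(n, config$distance_range[1],
                                           config$distance_range[2]), 2),
    creek = sample(c("broken", "boosey", "nine_mile"), n, replace = TRUE),
    area = round(stats::runif(n, config$area_range[1], config$area_range[2]), 2),
    road = sample(0:1, n, TRUE, prob = c(0.5, 0.5)),
    cropping = sample(0:1, n, TRUE, prob = c(0.6, 0.4)),
    grazing = sample(0:1, n, TRUE, prob = c(0.4, 0.6)),
    water = sample(0:1, n, TRUE, prob = c(0.5, 0.5)),
    days_offset = as.integer(round(stats::runif(n, config$days_range[1],
                                                config$days_range[2]))),
    licence_t1 = mg[, 1], fence_t1 = mg[, 2],
    licence_t2 = mg[, 3], fence_t2 = mg[, 4]
  )
  k <- max(1L, round(n * config$calibration_fraction))
  sites$calibration <- seq_len(n) %in% sample(n, k)
  sites
}

# subjective historical states and pre-misclassification scores, per attribute
draw_subjective <- function(n, attr, config) {
  reg <- config$registry[[attr]]
  if (reg$scale == "proportion") {
    bare <- 100 * stats::rbeta(n, 1.5, 8)
    fifty <- 100 * stats::rbeta(n, 1.5, 10)
    # keep at least 5% for the native/weedy split
    shrink <- pmin(95 / (bare + fifty), 1)
    bare <- bare * shrink; fifty <- fifty * shrink
    frac <- stats::rbeta(n, config$beta_shape1, config$beta_shape2)
    mostly_native <- frac * (100 - bare - fifty)
    list(value = mostly_native,              # percent, continuous
         parts = data.frame(mostly_native = mostly_native,
                            mostly_weedy = 100 - bare - fifty - mostly_native,
                            fifty_fifty = fifty, bare = bare))
  } else {
    zero <- stats::runif(n) < config$density_zero_prob
    v <- stats::rgamma(n, shape = config$density_shape,
                       scale = config$density_scale)
    v[zero] <- 0
    list(value = v, parts = NULL)
  }
}

# link-scale support of the scored category (shared by generator and models)
latent_support <- function(spec, score, config) {
  if (spec$scale == "proportion") {
    b <- category_bounds(spec, score) / 100
    lo <- pmax(b[[1]], config$p_floor); hi <- pmin(b[[2]], 1 - config$p_floor)
    c(link_transform(lo, "cloglog"), link_transform(hi, "cloglog"))
  } else {
    b <- category_bounds(spec, score)
    if (b[[1]] == b[[2]]) {                  # "None": below-detection interval
      b <- c(0, spec$zero_cap)
    }
    lo <- max(b[[1]], config$d_floor)
    c(log(lo), log(b[[2]]))
  }
}

#' Generate true site states
#'
#' Draws subjective historical states, pushes them through the true
#' calibration regression to obtain the objective historical value
#' (`value_t1`), applies site change \eqn{\alpha_i \sim N(\mu, \sigma)} plus
#' the season contribution \eqn{\gamma T_i} on the link scale, and records
#' the objective contemporary value (`value_t2`). In `"from_model"` mode the
#' latent predictor behind each score is redrawn uniformly within the scored
#' category on the link scale, so the data are an exact ancestral simulation
#' of the model graph.
#'
#' @param sites from [generate_sites()].
#' @param config a [generator_config()].
#' @return data.frame with one row per site and attribute: `subj_t1`
#'   (perceived subjective state), `score_t1` (categorical score before any
#'   misclassification), `value_t1`, `value_t2`, `alpha`,
#'   `season_contrib`, and the latent link-scale predictor `v1`.
#' @export
generate_true_states <- function(sites, config) {
  set.seed(config$seed + 1L)
  n <- nrow(sites)
  x <- site_covariate(sites)
  out <- list()
  for (attr in config$attributes) {
    reg <- config$registry[[attr]]
    pp <- config$params[[attr]]
    sub <- draw_subjective(n, attr, config)
    score <- score_value(reg, sub$value)
    if (reg$scale == "proportion") {
      v1_obs <- link_transform(zero_adjust(sub$value / 100, epsilon = config$p_floor),
                               "cloglog")
    } else {
      v1_obs <- log(pmax(sub$value, config$d_floor))
    }
    if (config$mode == "from_model") {
      supp <- t(vapply(score, function(s) latent_support(reg, s, config),
                       numeric(2)))
      v1 <- stats::runif(n, supp[, 1], supp[, 2])
    } else {
      v1 <- v1_obs
    }
    eps <- stats::rnorm(n, 0, pp$sd_eta)
    lr <- pp$a + pp$b * v1 + pp$c * x + eps
    alpha <- stats::rnorm(n, pp$mu, pp$sigma)
    season <- pp$gamma * sites$days_offset
    lp <- lr + alpha + season
    if (reg$scale == "proportion") {
      value_t1 <- inverse_link(lr, "cloglog")
      value_t2 <- inverse_link(lp, "cloglog")
    } else {
      value_t1 <- exp(lr)
      value_t2 <- exp(lp)
      if (config$pulse_prob > 0) {
        # episodic recruitment at historically bare sites; alpha is
        # recomputed so the link arithmetic of the truth table stays exact
        hit <- sub$value == 0 & stats::runif(n) < config$pulse_prob
        if (any(hit)) {
          value_t2[hit] <- value_t2[hit] +
            stats::rgamma(sum(hit), 2, scale = config$pulse_density / 2)
          alpha[hit] <- log(value_t2[hit]) - log(value_t1[hit]) - season[hit]
        }
      }
    }
    df <- data.frame(site_id = sites$site_id, attribute = attr,
                     subj_t1 = sub$value, score_t1 = score,
                     v1 = v1, value_t1 = value_t1, value_t2 = value_t2,
                     alpha = alpha, season_contrib = season)
    parts <- if (is.null(sub$parts)) {
      as.data.frame(matrix(NA_real_, n, 4, dimnames = list(NULL,
        c("part_mostly_native", "part_mostly_weedy", "part_fifty_fifty",
          "part_bare"))))
    } else {
      stats::setNames(sub$parts, paste0("part_", names(sub$parts)))
    }
    df <- cbind(df, parts)
    out[[attr]] <- df
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# round composition parts (percent) to the resolution grid, summing to 100,
# by largest-remainder apportionment
round_composition <- function(parts, resolution = 5) {
  units <- 100 / resolution
  raw <- pmax(as.numeric(parts), 0)
  raw <- raw / sum(raw) * units
  fl <- floor(raw)
  rem <- as.integer(units - sum(fl))
  if (rem > 0) {
    give <- order(raw - fl, decreasing = TRUE)[seq_len(rem)]
    fl[give] <- fl[give] + 1
  }
  fl * resolution
}

# adjacent-category misclassification on an ordinal or grid scale
misclassify <- function(score, spec, prob) {
  if (prob <= 0) return(score)
  flip <- stats::runif(length(score)) < prob
  if (!any(flip)) return(score)
  if (!is.null(spec$categories)) {
    top <- max(vapply(spec$categories, `[[`, integer(1), "code"))
    step <- ifelse(score == 0, 1L, ifelse(score == top, -1L,
                   sample(c(-1L, 1L), length(score), TRUE)))
  } else {
    step <- ifelse(score == 0, spec$resolution,
                   ifelse(score == 100, -spec$resolution,
                   sample(c(-1, 1), length(score), TRUE) * spec$resolution))
  }
  score[flip] <- score[flip] + step[flip]
  score
}

#' Generate the historical categorical survey
#'
#' Scores each site's subjective historical state on the attribute's
#' categorical scale. Density scores can be flipped to an adjacent category
#' with the configured misclassification probability; nativeness composition
#' parts are rounded to the scoring grid (largest-remainder, summing to 100)
#' after optional misclassification of the mostly-native part.
#'
#' @param true_states from [generate_true_states()].
#' @param config a [generator_config()].
#' @return data.frame in the `historical` table layout of [survey_data()].
#' @export
generate_historical_survey <- function(true_states, config) {
  set.seed(config$seed + 2L)
  out <- list()
  for (attr in unique(true_states$attribute)) {
    reg <- config$registry[[attr]]
    ts <- true_states[true_states$attribute == attr, ]
    if (reg$scale == "proportion") {
      comp <- t(apply(ts[, paste0("part_", reg$composition)], 1,
                      round_composition, resolution = reg$resolution))
      colnames(comp) <- reg$composition
      mn <- misclassify(comp[, "mostly_native"], reg, config$misclass_prob)
      shift <- mn - comp[, "mostly_native"]
      shift[comp[, "mostly_weedy"] - shift < 0] <- 0  # keep parts non-negative
      comp[, "mostly_native"] <- comp[, "mostly_native"] + shift
      comp[, "mostly_weedy"] <- comp[, "mostly_weedy"] - shift
      df <- data.frame(site_id = ts$site_id, attribute = attr, score = NA_integer_)
      df <- cbind(df, as.data.frame(comp))
    } else {
      sc <- misclassify(ts$score_t1, reg, config$misclass_prob)
      df <- data.frame(site_id = ts$site_id, attribute = attr, score = sc,
                       mostly_native = NA_real_, mostly_weedy = NA_real_,
                       fifty_fifty = NA_real_, bare = NA_real_)
    }
    out[[attr]] <- df
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Generate the quantitative contemporary survey
#'
#' Point-intercept hits are binomial draws around the true contemporary
#' proportion, with points per site drawn from a clipped lognormal matching
#' the observed median and range. Tree counts are Poisson draws with the
#' sampled belt-quadrat area (transects of 6-173 m, 4 m belt) as offset.
#'
#' @param true_states from [generate_true_states()].
#' @param sites from [generate_sites()].
#' @param config a [generator_config()].
#' @return data.frame in the `contemporary` table layout of [survey_data()].
#' @export
generate_contemporary_survey <- function(true_states, sites, config) {
  set.seed(config$seed + 3L)
  n <- nrow(sites)
  out <- list()
  for (attr in unique(true_states$attribute)) {
    reg <- config$registry[[attr]]
    ts <- true_states[true_states$attribute == attr, ]
    ts <- ts[match(sites$site_id, ts$site_id), ]
    if (reg$scale == "proportion") {
      pts <- draw_points(n, config)
      p2 <- pmin(pmax(ts$value_t2, 1e-9), 1 - 1e-9)
      df <- data.frame(site_id = sites$site_id, attribute = attr,
                       hits = stats::rbinom(n, pts, p2), points = pts,
                       count = NA_integer_, sampled_area = NA_real_)
    } else {
      ntr <- sample(2:8, n, replace = TRUE)
      area <- vapply(ntr, function(k) sum(stats::runif(k, 6, 173)) * 4 / 1e4,
                     numeric(1))
      df <- data.frame(site_id = sites$site_id, attribute = attr,
                       hits = NA_integer_, points = NA_integer_,
                       count = stats::rpois(n, area * ts$value_t2),
                       sampled_area = round(area, 4))
    }
    out[[attr]] <- df
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

draw_points <- function(n, config) {
  pts <- round(stats::rlnorm(n, log(config$points_median), 0.45))
  as.integer(pmin(pmax(pts, config$points_range[1]), config$points_range[2]))
}

#' Generate the double-sampled calibration survey
#'
#' At each flagged site the historical survey method is re-applied to the
#' contemporary vegetation state within two weeks of the contemporary
#' survey. In `"observer"` mode the perceived state is the inverse of the
#' true calibration regression at the site's contemporary value (with a
#' fresh between-site deviation), and the pair's quantitative record is the
#' site's contemporary observation. In `"from_model"` mode both the score
#' and a separate quantitative response are simulated ancestrally from the
#' calibration block of the model graph.
#'
#' @param true_states from [generate_true_states()].
#' @param sites from [generate_sites()] (uses the `calibration` flags).
#' @param contemporary from [generate_contemporary_survey()].
#' @param config a [generator_config()].
#' @return data.frame in the `calibration` table layout of [survey_data()].
#' @export
generate_calibration_survey <- function(true_states, sites, contemporary,
                                        config) {
  set.seed(config$seed + 4L)
  flagged <- sites[sites$calibration, ]
  xall <- site_covariate(sites)
  out <- list()
  for (attr in unique(true_states$attribute)) {
    reg <- config$registry[[attr]]
    pp <- config$params[[attr]]
    ts <- true_states[true_states$attribute == attr, ]
    ts <- ts[match(flagged$site_id, ts$site_id), ]
    x <- xall[sites$calibration]
    k <- nrow(flagged)
    eta <- stats::rnorm(k, 0, pp$sd_eta)
    link <- if (reg$scale == "proportion") "cloglog" else "log"
    if (config$mode == "observer") {
      lq <- link_transform(
        if (reg$scale == "proportion") {
          zero_adjust(ts$value_t2, epsilon = config$p_floor)
        } else zero_adjust(ts$value_t2, epsilon = config$d_floor), link)
      v1c <- (lq - pp$a - pp$c * x - eta) / pp$b
      perceived <- if (reg$scale == "proportion") {
        100 * inverse_link(v1c, "cloglog")
      } else exp(v1c)
      qk <- ts$value_t2
    } else {
      sub <- draw_subjective(k, attr, config)
      perceived <- sub$value
      score0 <- score_value(reg, perceived)
      supp <- t(vapply(score0, function(s) latent_support(reg, s, config),
                       numeric(2)))
      v1c <- stats::runif(k, supp[, 1], supp[, 2])
      qk <- inverse_link(pp$a + pp$b * v1c + pp$c * x + eta, link)
    }
    sc <- score_value(reg, if (reg$scale == "proportion") {
      pmin(pmax(perceived, 0), 100)
    } else pmax(perceived, 0))
    sc <- misclassify(sc, reg, config$misclass_prob)
    df <- data.frame(site_id = flagged$site_id, attribute = attr)
    if (reg$scale == "proportion") {
      remainder <- 100 - sc
      df$score <- NA_integer_
      df$mostly_native <- sc
      # residual parts: simple split of the remainder on the grid
      df$bare <- round_to(remainder * 0.15, reg$resolution)
      df$fifty_fifty <- round_to(remainder * 0.1, reg$resolution)
      df$mostly_weedy <- remainder - df$bare - df$fifty_fifty
    } else {
      df$score <- sc
      df$mostly_native <- NA_real_; df$mostly_weedy <- NA_real_
      df$fifty_fifty <- NA_real_; df$bare <- NA_real_
    }
    co <- contemporary[contemporary$attribute == attr, ]
    co <- co[match(flagged$site_id, co$site_id), ]
    if (config$mode == "observer") {
      df$hits <- co$hits; df$points <- co$points
      df$count <- co$count; df$sampled_area <- co$sampled_area
    } else {
      if (reg$scale == "proportion") {
        m <- draw_points(k, config)
        df$hits <- stats::rbinom(k, m, pmin(pmax(qk, 1e-9), 1 - 1e-9))
        df$points <- m
        df$count <- NA_integer_; df$sampled_area <- NA_real_
      } else {
        df$hits <- NA_integer_; df$points <- NA_integer_
        df$count <- stats::rpois(k, co$sampled_area * qk)
        df$sampled_area <- co$sampled_area
      }
    }
    df$offset_days <- sample(-14:14, k, replace = TRUE)
    out[[attr]] <- df
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

round_to <- function(x, resolution) round(x / resolution) * resolution

#' Simulate a complete survey dataset
#'
#' Orchestrates [generate_sites()], [generate_true_states()],
#' [generate_historical_survey()], [generate_contemporary_survey()] and
#' [generate_calibration_survey()] into a validated [survey_data()] object
#' with the truth table attached as `$truth`.
#'
#' @param config a [generator_config()].
#' @return a `survey_data` object with `$truth`.
#' @examples
#' d <- simulate_survey(generator_config(n_sites = 30, seed = 7,
#'                                       attributes = "nativeness"))
#' d
#' @export
simulate_survey <- function(config = generator_config()) {
  sites <- generate_sites(config)
  truth <- generate_true_states(sites, config)
  hist <- generate_historical_survey(truth, config)
  cont <- generate_contemporary_survey(truth, sites, config)
  cal <- generate_calibration_survey(truth, sites, cont, config)
  x <- survey_data(sites, hist, cont, cal)
  x$truth <- truth
  x$config <- config
  x
}
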