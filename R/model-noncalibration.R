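#' Build the non-calibration (Bayesian reinterpretation) model
#'
#' The alternative to calibration by double sampling: no double-sampled
#' pairs are used, and the historical value is constrained only by the
#' informative prior implied by its categorical score. For proportion
#' attributes the response is the cloglog-transformed observed cover
#' proportion, modelled as normal around the latent historical value plus
#' change; the residual SD gets a weakly-informative half-normal prior. For
#' density attributes the contemporary counts are Poisson with an area
#' offset and log-rate equal to the log latent historical density plus
#' change. Change is \eqn{\delta_i = \alpha_i + \gamma T_i} with
#' \eqn{\alpha_i \sim N(\mu, \sigma)}, exactly as in the calibration model.
#'
#' The function takes no calibration table: its absence is the defining
#' feature of the approach.
#'
#' @param data a [survey_data()] object; the calibration table is ignored
#'   and never read.
#' @param attribute registry attribute to model.
#' @param prior_form prior on the latent historical value (see
#'   [prior_spec()]); `"normal"` and `"truncated_normal"` take their moments
#'   from the contemporary data unless `reference` is supplied.
#' @param reference optional numeric vector of reference values (natural
#'   scale) for the normal moments; defaults to the attribute's contemporary
#'   values.
#' @param season include the day-of-year coefficient (default: proportion
#'   attributes only).
#' @param registry attribute registry.
#' @param p_floor,d_floor link-transform floors.
#' @return a `vc_model` (see [build_calibration_change_model()]).
#' @export
build_noncalibration_model <- function(data, attribute,
                                       prior_form = "truncated_normal",
                                       reference = NULL, season = NULL,
                                       registry = attribute_registry(),
                                       p_floor = 5e-4, d_floor = 0.05) {
  spec <- registry[[attribute]]
  if (is.null(spec)) stop("unknown attribute ", attribute, call. = FALSE)
  if (is.null(season)) season <- spec$scale == "proportion"
  prior_form <- match.arg(prior_form,
                          c("midpoint", "uniform", "normal", "truncated_normal"))

  sites <- data$sites
  cont <- data$contemporary[data$contemporary$attribute == attribute, ]
  cont <- cont[match(sites$site_id, cont$site_id), ]
  hist <- data$historical[data$historical$attribute == attribute, ]
  hist <- hist[match(sites$site_id, hist$site_id), ]
  N <- nrow(sites)

  lspec <- if (spec$scale == "proportion") composition_part_spec(spec) else spec
  score <- if (spec$scale == "proportion") hist$mostly_native else hist$score
  bb <- t(vapply(score, function(s) prior_support(s, lspec, p_floor, d_floor),
                 numeric(2)))
  vmid <- vapply(score, function(s) {
    midpoint_prior(s, lspec, p_floor, d_floor)$support[1]
  }, numeric(1))

  jd <- list(N = N, Td = sites$days_offset)
  if (spec$family == "binomial_cloglog") {
    prop <- zero_adjust(cont$hits / cont$points, points = cont$points)
    jd$z <- link_transform(prop, "cloglog")
    reflink <- jd$z
  } else {
    jd$Y <- cont$count; jd$area <- cont$sampled_area
    refvals <- if (is.null(reference)) {
      zero_adjust(cont$count / cont$sampled_area, area = cont$sampled_area)
    } else reference
    reflink <- log(pmax(refvals, d_floor))
  }
  if (spec$family == "binomial_cloglog" && !is.null(reference)) {
    reflink <- link_transform(zero_adjust(reference, epsilon = p_floor),
                              "cloglog")
  }
  v_data <- NULL
  if (prior_form == "midpoint") {
    jd$v <- vmid; v_data <- vmid
  } else {
    if (prior_form %in% c("uniform", "truncated_normal")) {
      jd$L <- bb[, 1]; jd$U <- bb[, 2]
    }
    if (prior_form %in% c("normal", "truncated_normal")) {
      if (length(unique(reflink)) < 2) {
        stop("degenerate reference for normal moments", call. = FALSE)
      }
      jd$ref_mu <- mean(reflink); jd$ref_tau <- 1 / stats::var(reflink)
    }
  }
  code <- jags_code_noncal(spec$family, prior_form, season)
  monitors <- c("mu", "sigma", if (season) "gamma",
                if (spec$family == "binomial_cloglog") "sd_res",
                "alpha", "p", if (prior_form != "midpoint") "v")
  structure(list(code = code, data = jd, monitors = monitors,
                 meta = list(kind = "noncalibration", attribute = attribute,
                             family = spec$family, link = "cloglog",
                             prior_form = prior_form, season = season,
                             site_ids = sites$site_id, v_data = v_data,
                             Td = sites$days_offset, spec = spec)),
            class = "vc_model")
}

latent_decl_1d <- function(prior_form) {
  switch(prior_form,
    midpoint = NULL,
    uniform = "    v[i] ~ dunif(L[i], U[i])",
    normal = "    v[i] ~ dnorm(ref_mu, ref_tau)",
    truncated_normal = "    v[i] ~ dnorm(ref_mu, ref_tau) T(L[i], U[i])"
  )
}

jags_code_noncal <- function(family, prior_form, season) {
  binom <- family == "binomial_cloglog"
  lines <- c(
    "model {",
    "  mu ~ dnorm(0, 1.0E-2)",
    "  sigma ~ dunif(0, 3)",
    "  tau_alpha <- pow(sigma, -2)",
    if (season) "  gamma ~ dnorm(0, 1.0E2)",
    if (binom) c("  sd_res ~ dnorm(0, 1) T(0, )",
                 "  tau_res <- pow(sd_res, -2)"),
    "  for (i in 1:N) {",
    latent_decl_1d(prior_form),
    "    alpha[i] ~ dnorm(mu, tau_alpha)",
    sprintf("    lp[i] <- v[i] + alpha[i]%s",
            if (season) " + gamma * Td[i]" else ""),
    if (binom) {
      c("    z[i] ~ dnorm(lp[i], tau_res)",
        "    p[i] <- 1 - exp(-exp(lp[i]))")
    } else {
      c("    log(p[i]) <- lp[i]",
        "    Y[i] ~ dpois(p[i] * area[i])")
    },
    "  }",
    "}"
  )
  paste(Filter(Negate(is.null), lines), collapse = "\n")
}

#' Compare per-site change estimates across prior forms
#'
#' Fits the non-calibration model under each requested prior form on the
#' same dataset and aligns the per-site posterior percentage-of-historical
#' point estimates, for pairwise comparison of the forms.
#'
#' @param data a [survey_data()].
#' @param attribute registry attribute.
#' @param forms prior forms to compare (>= 2).
#' @param config a [fit_config()].
#' @param ... passed to [build_noncalibration_model()].
#' @return data.frame with `site_id` and one percentage-change column per
#'   form.
#' @export
compare_prior_forms <- function(data, attribute,
                                forms = c("midpoint", "uniform",
                                          "truncated_normal"),
                                config = fit_config(), ...) {
  if (length(forms) < 2) stop("need >= 2 prior forms", call. = FALSE)
  out <- NULL
  for (f in forms) {
    model <- build_noncalibration_model(data, attribute, prior_form = f, ...)
    fit <- fit_model(model, config)
    cs <- summarize_change(fit, model)
    df <- cs$sites[, c("site_id", "mean")]
    names(df)[2] <- f
    out <- if (is.null(out)) df else merge(out, df, by = "site_id", sort = FALSE)
  }
  out
}
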