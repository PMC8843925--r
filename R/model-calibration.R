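#' Build the joint calibration-prediction-change model
#'
#' Assembles the three-part hierarchical model as a JAGS model specification:
#'
#' \describe{
#'   \item{Calibration}{at double-sampled sites \eqn{k}, the quantitative
#'     contemporary response (`R_k` hits from `m_k` points, or a count with
#'     an area offset) is regressed on the link-transformed latent value
#'     behind the simultaneously collected categorical score, plus scaled
#'     site covariates, with intercept \eqn{a}, coefficients \eqn{(b, c)}
#'     and a between-site deviation \eqn{\eta_k \sim N(0, \sigma_\eta)}.}
#'   \item{Prediction}{the same intercept and coefficients applied to the
#'     latent values behind the historical scores give the calibrated
#'     historical value \eqn{r_i}, with a site deviation \eqn{\epsilon_i}
#'     sharing \eqn{\sigma_\eta}.}
#'   \item{Change}{on the link scale,
#'     \eqn{\mathrm{link}(p_i) = \mathrm{link}(r_i) + \delta_i} with
#'     \eqn{\delta_i = \alpha_i + \gamma T_i},
#'     \eqn{\alpha_i \sim N(\mu, \sigma)}, and the contemporary observations
#'     are binomial (hits from points) or Poisson (counts with area offset)
#'     around \eqn{p_i}.}
#' }
#'
#' Latent historical predictor values carry the selected informative prior
#' form (see [prior_spec()]). Hits always enter as counts from points, never
#' as pre-computed proportions. For sampling efficiency the two site-level
#' normal deviations of the prediction and change layers are marginalised
#' into one (\eqn{w_i = \epsilon_i + \alpha_i}); [summarize_change()]
#' reconstructs the split analytically when per-site historical values are
#' needed.
#'
#' @param data a [survey_data()] object with a calibration table.
#' @param attribute which registry attribute to model.
#' @param prior_form prior on latent historical predictor values:
#'   `"midpoint"`, `"uniform"`, `"normal"` or `"truncated_normal"`.
#' @param site_covariates character vector of site-table columns entered as
#'   covariates; continuous ones are centred and divided by two SDs.
#' @param include_attribute include the subjective attribute counterpart as
#'   the (latent) primary predictor; `FALSE` gives the intercept-only null
#'   model used for model selection.
#' @param include_weedy for nativeness only: also include the mostly-weedy
#'   composition part as a second latent predictor.
#' @param include_site_effect include the between-site deviation
#'   \eqn{\eta_k} in the calibration block; the intercept-only null used in
#'   model-selection tables omits it.
#' @param link link for proportion attributes (`"cloglog"` default;
#'   `"logit"` retained as an alternative).
#' @param season include the day-of-year offset coefficient \eqn{\gamma};
#'   defaults to `TRUE` for proportion (cover) attributes and `FALSE` for
#'   tree densities.
#' @param registry attribute registry.
#' @param p_floor,d_floor link-transform floors (see [generator_config()]).
#' @return an object of class `vc_model`: the JAGS model `code`, `data`
#'   list, `monitors`, and `meta` needed by downstream summaries.
#' @export
build_calibration_change_model <- function(data, attribute,
                                           prior_form = "truncated_normal",
                                           site_covariates = character(),
                                           include_attribute = TRUE,
                                           include_weedy = FALSE,
                                           include_site_effect = TRUE,
                                           link = c("cloglog", "logit"),
                                           season = NULL,
                                           registry = attribute_registry(),
                                           p_floor = 5e-4, d_floor = 0.05) {
  link <- match.arg(link)
  spec <- registry[[attribute]]
  if (is.null(spec)) stop("unknown attribute ", attribute, call. = FALSE)
  if (is.null(data$calibration) || !nrow(data$calibration)) {
    stop("calibration model requires a calibration table", call. = FALSE)
  }
  if (is.null(season)) season <- spec$scale == "proportion"
  prior_form <- match.arg(prior_form,
                          c("midpoint", "uniform", "normal", "truncated_normal"))

  prep <- prep_model_frames(data, attribute, spec, site_covariates,
                            include_attribute, include_weedy, prior_form,
                            p_floor, d_floor)
  fam <- spec$family
  code <- jags_code_joint(fam, prior_form, J = prep$J, P = prep$P,
                          season = season, link = link,
                          site_effect = include_site_effect)
  monitors <- c("a", if (prep$J > 0) "b", if (prep$P > 0) "c",
                "sd_eta", "mu", "sigma", if (season) "gamma",
                "w", "q", "p", if (prep$J > 0 && prior_form != "midpoint") "v")
  structure(list(code = code, data = prep$jags_data, monitors = monitors,
                 meta = list(kind = "calibration", attribute = attribute,
                             family = fam, link = link,
                             prior_form = prior_form, season = season,
                             J = prep$J, P = prep$P,
                             site_ids = prep$site_ids,
                             calibration_ids = prep$calibration_ids,
                             v_data = prep$v_data, Td = prep$Td,
                             scaling = prep$scaling,
                             spec = spec)),
            class = "vc_model")
}

# ---- shared data preparation -------------------------------------------------

latent_names_for <- function(spec, include_attribute, include_weedy) {
  if (!include_attribute) return(character())
  if (spec$scale == "proportion") {
    c("mostly_native", if (include_weedy) "mostly_weedy")
  } else {
    spec$name
  }
}

latent_scores <- function(tab, latent, spec) {
  if (spec$scale == "proportion") tab[[latent]] else tab$score
}

# proportion-scale spec used for composition-part latents
composition_part_spec <- function(spec) {
  attribute_spec(name = spec$name, scale = "proportion",
                 family = "binomial_cloglog", composition = spec$composition,
                 resolution = spec$resolution)
}

prep_model_frames <- function(data, attribute, spec, site_covariates,
                              include_attribute, include_weedy, prior_form,
                              p_floor, d_floor) {
  sites <- data$sites
  cont <- data$contemporary[data$contemporary$attribute == attribute, ]
  cont <- cont[match(sites$site_id, cont$site_id), ]
  hist <- data$historical[data$historical$attribute == attribute, ]
  hist <- hist[match(sites$site_id, hist$site_id), ]
  cal <- data$calibration[data$calibration$attribute == attribute, ]
  if (any(is.na(match(cal$site_id, sites$site_id)))) {
    stop("calibration site not in site table", call. = FALSE)
  }
  N <- nrow(sites); K <- nrow(cal)

  # covariates: continuous ones centred / divided by 2 SD, binaries untouched
  cont_cov <- intersect(site_covariates, c("distance_upstream", "area"))
  scaling <- NULL
  sx <- sites
  if (length(cont_cov)) {
    sc <- scale_predictors(sites, cont_cov)
    sx <- sc$data; scaling <- sc$scaling
  }
  X <- if (length(site_covariates)) {
    as.matrix(sx[, site_covariates, drop = FALSE])
  } else NULL
  Xc <- if (length(site_covariates)) {
    X[match(cal$site_id, sites$site_id), , drop = FALSE]
  } else NULL

  latents <- latent_names_for(spec, include_attribute, include_weedy)
  J <- length(latents)
  cfg <- list(p_floor = p_floor, d_floor = d_floor)  # mimics generator floors
  bounds <- function(tab) {
    if (!J) return(NULL)
    L <- U <- Vmid <- matrix(NA_real_, nrow(tab), J)
    for (j in seq_len(J)) {
      lspec <- if (spec$scale == "proportion") composition_part_spec(spec) else spec
      sc <- latent_scores(tab, latents[j], spec)
      bb <- t(vapply(sc, function(s) prior_support(s, lspec, p_floor, d_floor),
                     numeric(2)))
      L[, j] <- bb[, 1]; U[, j] <- bb[, 2]
      Vmid[, j] <- vapply(sc, function(s) {
        midpoint_prior(s, lspec, p_floor, d_floor)$support[1]
      }, numeric(1))
    }
    list(L = L, U = U, mid = Vmid)
  }
  bh <- bounds(hist); bc <- bounds(cal)

  jd <- list(N = N, K = K)
  if (spec$family == "binomial_cloglog") {
    jd$Y <- cont$hits; jd$n <- cont$points
    jd$R <- cal$hits; jd$m <- cal$points
    refvals <- zero_adjust(cont$hits / cont$points, points = cont$points)
    reflink <- link_transform(refvals, "cloglog")
  } else {
    jd$Y <- cont$count; jd$area <- cont$sampled_area
    jd$R <- cal$count; jd$area_cal <- cal$sampled_area
    refvals <- zero_adjust(cont$count / cont$sampled_area,
                           area = cont$sampled_area)
    reflink <- log(refvals)
  }
  Td <- sites$days_offset
  jd$Td <- Td
  if (!is.null(X)) { jd$X <- X; jd$Xc <- Xc }
  v_data <- NULL
  if (J > 0) {
    jd$cmid <- colMeans((bh$L + bh$U) / 2)
    if (prior_form == "midpoint") {
      jd$v <- bh$mid; jd$vc <- bc$mid
      v_data <- bh$mid
    } else {
      if (prior_form %in% c("uniform", "truncated_normal")) {
        jd$L <- bh$L; jd$U <- bh$U; jd$CL <- bc$L; jd$CU <- bc$U
      }
      if (prior_form %in% c("normal", "truncated_normal")) {
        # reference moments; second (weedy) latent uses the complement cover
        refm <- numeric(J); reft <- numeric(J)
        for (j in seq_len(J)) {
          rv <- if (J > 1 && latents[j] == "mostly_weedy") {
            if (spec$family == "binomial_cloglog") {
              link_transform(zero_adjust(1 - cont$hits / cont$points,
                                         points = cont$points), "cloglog")
            } else reflink
          } else reflink
          refm[j] <- mean(rv); reft[j] <- 1 / stats::var(rv)
        }
        jd$ref_mu <- refm; jd$ref_tau <- reft
      }
    }
  }
  list(jags_data = jd, J = J, P = if (is.null(X)) 0L else ncol(X),
       site_ids = sites$site_id, calibration_ids = cal$site_id,
       v_data = v_data, Td = Td, scaling = scaling)
}

# ---- JAGS code generation ----------------------------------------------------

latent_decl <- function(prior_form, var, idx, Lv, Uv) {
  switch(prior_form,
    midpoint = NULL,  # latents enter as data
    uniform = sprintf("    %s[%s, j] ~ dunif(%s[%s, j], %s[%s, j])",
                      var, idx, Lv, idx, Uv, idx),
    normal = sprintf("    %s[%s, j] ~ dnorm(ref_mu[j], ref_tau[j])",
                     var, idx),
    truncated_normal = sprintf(
      "    %s[%s, j] ~ dnorm(ref_mu[j], ref_tau[j]) T(%s[%s, j], %s[%s, j])",
      var, idx, Lv, idx, Uv, idx)
  )
}

lin_pred <- function(J, P, var, xvar, idx) {
  # `a` is the deterministic uncentred intercept; sampling runs on the
  # centred `ac`, which decorrelates the intercept from the latent slopes
  terms <- "a"
  if (J > 0) terms <- c(terms, sprintf("inprod(b[], %s[%s, ])", var, idx))
  if (P > 0) terms <- c(terms, sprintf("inprod(c[], %s[%s, ])", xvar, idx))
  paste(terms, collapse = " + ")
}

jags_code_joint <- function(family, prior_form, J, P, season, link,
                            site_effect = TRUE) {
  binom <- family == "binomial_cloglog"
  linkfun <- if (binom) link else "log"
  eta_term <- if (site_effect) " + eta[k]" else ""
  lines <- c(
    "model {",
    "  ac ~ dnorm(0, 1.0E-2)",
    if (J > 0) sprintf("  for (j in 1:%d) { b[j] ~ dnorm(0, 1.0E-2) }", J),
    if (P > 0) sprintf("  for (h in 1:%d) { c[h] ~ dnorm(0, 1.0E-2) }", P),
    "  sd_eta ~ dunif(0, 3)",
    "  tau_eta <- pow(sd_eta, -2)",
    "  mu ~ dnorm(0, 1.0E-2)",
    "  sigma ~ dunif(0, 3)",
    "  tau_w <- 1 / (pow(sigma, 2) + pow(sd_eta, 2))",
    if (season) "  gamma ~ dnorm(0, 1.0E2)",
    if (J > 0) "  a <- ac - inprod(b[], cmid[])" else "  a <- ac",
    "  for (k in 1:K) {",
    if (J > 0) {
      lk <- latent_decl(prior_form, "vc", "k", "CL", "CU")
      if (!is.null(lk)) sprintf("    for (j in 1:%d) {\n  %s\n    }", J, lk)
    },
    if (site_effect) "    eta[k] ~ dnorm(0, tau_eta)",
    if (binom) {
      c(sprintf("    %s(q[k]) <- %s%s", linkfun,
                lin_pred(J, P, "vc", "Xc", "k"), eta_term),
        "    R[k] ~ dbin(q[k], m[k])")
    } else {
      c(sprintf("    log(q[k]) <- %s%s", lin_pred(J, P, "vc", "Xc", "k"),
                eta_term),
        "    R[k] ~ dpois(q[k] * area_cal[k])")
    },
    "  }",
    "  for (i in 1:N) {",
    if (J > 0) {
      li <- latent_decl(prior_form, "v", "i", "L", "U")
      if (!is.null(li)) sprintf("    for (j in 1:%d) {\n  %s\n    }", J, li)
    },
    "    w[i] ~ dnorm(mu, tau_w)",
    sprintf("    lp[i] <- %s + w[i]%s", lin_pred(J, P, "v", "X", "i"),
            if (season) " + gamma * Td[i]" else ""),
    if (binom) {
      c(sprintf("    %s(p[i]) <- lp[i]", linkfun),
        "    Y[i] ~ dbin(p[i], n[i])")
    } else {
      c("    log(p[i]) <- lp[i]",
        "    Y[i] ~ dpois(p[i] * area[i])")
    },
    "  }",
    "}"
  )
  paste(Filter(Negate(is.null), lines), collapse = "\n")
}

#' @export
print.vc_model <- function(x, ...) {
  cat("<vc_model>", x$meta$kind, "model:", x$meta$attribute,
      "|", x$meta$family, "| prior:", x$meta$prior_form, "\n")
  cat("  sites:", x$data$N, " calibration pairs:",
      if (is.null(x$data$K)) 0 else x$data$K, "\n")
  invisible(x)
}

#' Serialize a model specification to JSON
#'
#' Captures the model structure (attribute, family, link, prior form,
#' predictor dimensions, data sizes) for provenance manifests.
#'
#' @param model a `vc_model`.
#' @return a JSON string.
#' @export
model_spec_json <- function(model) {
  m <- model$meta
  jsonlite::toJSON(list(kind = m$kind, attribute = m$attribute,
                        family = m$family, link = m$link,
                        prior_form = m$prior_form, season = m$season,
                        n_latent_predictors = m$J, n_site_covariates = m$P,
                        n_sites = model$data$N,
                        n_calibration = if (is.null(model$data$K)) 0 else model$data$K),
                   auto_unbox = TRUE, pretty = TRUE)
}

#' Change expressed as a percentage of the historical value
#'
#' Back-transforms a contemporary and a historical draw to the natural scale
#' and expresses the contemporary value as a percentage of the historical
#' one: 100 means no change.
#'
#' @param contemporary,historical values (or posterior draws) on the natural
#'   scale.
#' @param epsilon optional small constant added to historical zeros; without
#'   it, a zero historical value is an error (the percentage is undefined).
#' @return percentages.
#' @examples
#' percentage_of_historical(0.4, 0.2)  # 200
#' @export
percentage_of_historical <- function(contemporary, historical, epsilon = NULL) {
  if (any(historical <= 0)) {
    if (is.null(epsilon)) {
      stop("historical value of 0 makes percentage change undefined; ",
           "supply `epsilon` to apply a small-constant adjustment",
           call. = FALSE)
    }
    historical <- pmax(historical, epsilon)
  }
  100 * contemporary / historical
}
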