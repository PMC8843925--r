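#' k-fold assignments
#'
#' Seeded near-equal disjoint folds covering all units.
#'
#' @param ids vector of unit identifiers.
#' @param k number of folds (2 <= k <= length(ids)).
#' @param seed integer seed.
#' @return integer vector of fold numbers, named by `ids`.
#' @export
kfold_split <- function(ids, k, seed = 1) {
  n <- length(ids)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of units", call. = FALSE)
  set.seed(seed)
  folds <- rep(seq_len(k), length.out = n)[sample.int(n)]
  stats::setNames(folds, ids)
}

#' Pearson correlation with a Fisher-z confidence interval
#'
#' \eqn{r} with the 95\% interval
#' \eqn{\tanh(\mathrm{atanh}(r) \pm z_{0.975}/\sqrt{n-3})}.
#'
#' @param x,y numeric vectors (n >= 4, both with nonzero variance).
#' @param conf confidence level.
#' @return list with `r`, `ci` (length 2) and `n`.
#' @export
pearson_with_ci <- function(x, y, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input has no defined correlation", call. = FALSE)
  }
  sx <- x - mean(x); sy <- y - mean(y)
  r <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
  z <- atanh(r)
  hw <- stats::qnorm((1 + conf) / 2) / sqrt(n - 3)
  list(r = r, ci = tanh(c(z - hw, z + hw)), n = n)
}

#' Cross-validate a change model
#'
#' Ten percent of units are held out per fold (with `k = 10`); each fold
#' refits the full model with the held-out quantitative responses treated as
#' missing, and the posterior mean of the corresponding observation-level
#' parameter is the prediction. Predictions are pooled across folds before
#' one Pearson correlation is computed (per-fold correlations are also
#' reported).
#'
#' For the calibration model the held-out units are the double-sampled
#' pairs' quantitative responses (predicting the contemporary value from the
#' historical-method score, within the whole calibration-change model); for
#' the non-calibration model the held-out units are the contemporary site
#' responses.
#'
#' @param data a [survey_data()].
#' @param attribute registry attribute.
#' @param method `"calibration"` or `"noncalibration"`.
#' @param prior_form informative prior form for latent historical values.
#' @param k number of folds.
#' @param config a [fit_config()].
#' @param rhat_exclude folds whose worst top-level R-hat exceeds this are
#'   flagged and excluded from pooling (severe non-convergence only).
#' @param ... passed to the model builder.
#' @return an object of class `vc_cv` with `predictions`, pooled `r` and
#'   `ci`, `per_fold` and `excluded`.
#' @export
crossvalidate <- function(data, attribute, method = c("calibration",
                                                      "noncalibration"),
                          prior_form = "truncated_normal", k = 10,
                          config = fit_config(), rhat_exclude = 2, ...) {
  method <- match.arg(method)
  if (method == "calibration") {
    units <- unique(data$calibration$site_id[
      data$calibration$attribute == attribute])
  } else {
    units <- data$sites$site_id
  }
  folds <- kfold_split(units, k, seed = config$seed)
  preds <- list(); excluded <- integer()
  for (f in seq_len(k)) {
    held <- names(folds)[folds == f]
    if (method == "calibration") {
      model <- build_calibration_change_model(data, attribute,
                                              prior_form = prior_form, ...)
      idx <- match(held, model$meta$calibration_ids)
      model$data$R[idx] <- NA
      obs_value <- if (model$meta$family == "binomial_cloglog") {
        model$data$m
      } else {
        model$data$area_cal
      }
      node <- "q"
    } else {
      model <- build_noncalibration_model(data, attribute,
                                          prior_form = prior_form, ...)
      idx <- match(held, model$meta$site_ids)
      if (model$meta$family == "binomial_cloglog") {
        model$data$z[idx] <- NA
      } else {
        model$data$Y[idx] <- NA
      }
      node <- "p"
    }
    fit <- suppressWarnings(fit_model(model, config))
    # exclusion is judged on the fold's predictive nodes: a badly mixing
    # variance split elsewhere does not invalidate the held-out predictions
    pred_cols <- paste0(node, "[", idx, "]")
    pred_rhat <- mcmc_diagnostics(fit$samples[, pred_cols, drop = FALSE])$rhat
    if (any(pred_rhat > rhat_exclude, na.rm = TRUE)) {
      warning("fold ", f, " excluded: prediction R-hat ",
              round(max(pred_rhat, na.rm = TRUE), 2), call. = FALSE)
      excluded <- c(excluded, f)
      next
    }
    m <- as.matrix(fit$samples)
    pred <- colMeans(m[, paste0(node, "[", idx, "]"), drop = FALSE])
    obs <- observed_values(data, attribute, held, method)
    preds[[f]] <- data.frame(site_id = held, fold = f, predicted = pred,
                             observed = obs, row.names = NULL)
  }
  preds <- do.call(rbind, preds)
  if (is.null(preds) || nrow(preds) < 4) {
    stop("too few converged folds to pool predictions", call. = FALSE)
  }
  pooled <- pearson_with_ci(preds$predicted, preds$observed)
  per_fold <- vapply(setdiff(seq_len(k), excluded), function(f) {
    d <- preds[preds$fold == f, ]
    if (nrow(d) < 4 || stats::sd(d$predicted) == 0 ||
        stats::sd(d$observed) == 0) return(NA_real_)
    pearson_with_ci(d$predicted, d$observed)$r
  }, numeric(1))
  structure(list(attribute = attribute, method = method,
                 prior_form = prior_form, folds = folds,
                 predictions = preds, r = pooled$r, ci = pooled$ci,
                 n = pooled$n, per_fold = per_fold, excluded = excluded),
            class = "vc_cv")
}

observed_values <- function(data, attribute, site_ids, method) {
  tab <- if (method == "calibration") data$calibration else data$contemporary
  tab <- tab[tab$attribute == attribute, ]
  tab <- tab[match(site_ids, tab$site_id), ]
  if (!all(is.na(tab$hits))) tab$hits / tab$points else tab$count / tab$sampled_area
}

#' @export
print.vc_cv <- function(x, ...) {
  cat("<vc_cv>", x$method, "model,", x$attribute, "| prior:", x$prior_form, "\n")
  cat(sprintf("  pooled Pearson r = %.3f (95%% CI %.3f, %.3f), n = %d\n",
              x$r, x$ci[1], x$ci[2], x$n))
  if (length(x$excluded)) cat("  excluded folds:", x$excluded, "\n")
  invisible(x)
}

# ---- change summaries --------------------------------------------------------

cri <- function(x, p) unname(stats::quantile(x, probs = p))

#' Summarise change as a percentage of the historical value
#'
#' For every posterior draw, back-transforms the calibrated historical value
#' \eqn{r_i} and the contemporary value \eqn{p_i} to the natural scale and
#' forms \eqn{100 p_i / r_i}; per-site and grand means with 50\% and 95\%
#' credible intervals summarise the draws (the point estimate is the
#' posterior mean of the percentage). For the calibration model the
#' prediction-side site deviation is reconstructed analytically from the
#' marginalised site term (see [build_calibration_change_model()]).
#'
#' @param fit a `vc_posterior`.
#' @param model the fitted `vc_model` (defaults to the one inside `fit`).
#' @param data optional [survey_data()] for management-class grouping.
#' @param group_by `"management"` to add grouped summaries.
#' @param seed seed for the analytic deviate reconstruction.
#' @return a `vc_change_summary`: `sites`, `grand`, and optionally `groups`
#'   data.frames.
#' @export
summarize_change <- function(fit, model = fit$model, data = NULL,
                             group_by = NULL, seed = 1) {
  m <- as.matrix(fit$samples)
  d <- model$data
  N <- d$N
  binom <- model$meta$family == "binomial_cloglog"
  p_draws <- m[, paste0("p[", seq_len(N), "]"), drop = FALSE]
  r_draws <- historical_draws(fit, model, m, seed)
  pct <- 100 * p_draws / r_draws
  site_sum <- data.frame(
    site_id = model$meta$site_ids,
    mean = colMeans(pct),
    q2.5 = apply(pct, 2, cri, 0.025), q25 = apply(pct, 2, cri, 0.25),
    q75 = apply(pct, 2, cri, 0.75), q97.5 = apply(pct, 2, cri, 0.975),
    row.names = NULL
  )
  grand_draws <- rowMeans(pct)
  grand <- data.frame(mean = mean(grand_draws),
                      q2.5 = cri(grand_draws, 0.025),
                      q25 = cri(grand_draws, 0.25),
                      q75 = cri(grand_draws, 0.75),
                      q97.5 = cri(grand_draws, 0.975))
  groups <- NULL
  if (!is.null(group_by) && group_by == "management") {
    if (is.null(data)) stop("management grouping needs the survey data",
                            call. = FALSE)
    cls <- assign_management_class(
      data$sites[match(model$meta$site_ids, data$sites$site_id), ])
    rows <- lapply(unique(cls), function(g) {
      idx <- which(cls == g)
      if (!length(idx)) return(NULL)
      gd <- rowMeans(pct[, idx, drop = FALSE])
      data.frame(class = g, n_sites = length(idx), mean = mean(gd),
                 q2.5 = cri(gd, 0.025), q25 = cri(gd, 0.25),
                 q75 = cri(gd, 0.75), q97.5 = cri(gd, 0.975))
    })
    groups <- do.call(rbind, rows)
  }
  structure(list(attribute = model$meta$attribute,
                 prior_form = model$meta$prior_form,
                 sites = site_sum, grand = grand, groups = groups),
            class = "vc_change_summary")
}

# natural-scale calibrated historical value r_i, per draw
historical_draws <- function(fit, model, m, seed = 1) {
  d <- model$data
  N <- d$N
  binom <- model$meta$family == "binomial_cloglog"
  inv <- function(x) {
    if (binom) inverse_link(x, model$meta$link) else exp(x)
  }
  if (model$meta$kind == "noncalibration") {
    v <- if (model$meta$prior_form == "midpoint") {
      matrix(rep(d$v, each = nrow(m)), nrow(m), N)
    } else {
      m[, paste0("v[", seq_len(N), "]"), drop = FALSE]
    }
    return(inv(v))
  }
  J <- model$meta$J
  lr0 <- matrix(rep(m[, "a"], N), nrow(m), N)
  if (J > 0) {
    bcols <- if (J == 1 && "b" %in% colnames(m)) "b" else paste0("b[", seq_len(J), "]")
    for (j in seq_len(J)) {
      vj <- if (model$meta$prior_form == "midpoint") {
        matrix(rep(model$meta$v_data[, j], each = nrow(m)), nrow(m), N)
      } else {
        m[, paste0("v[", seq_len(N), ",", j, "]"), drop = FALSE]
      }
      lr0 <- lr0 + m[, bcols[j]] * vj
    }
  }
  P <- model$meta$P
  if (P > 0) {
    ccols <- if (P == 1 && "c" %in% colnames(m)) "c" else paste0("c[", seq_len(P), "]")
    for (h in seq_len(P)) lr0 <- lr0 + outer(m[, ccols[h]], d$X[, h])
  }
  # split w = eps + alpha: eps | w ~ N((w - mu) k, k sigma^2), k = se^2/(se^2+sg^2)
  w <- m[, paste0("w[", seq_len(N), "]"), drop = FALSE]
  se2 <- m[, "sd_eta"]^2; sg2 <- m[, "sigma"]^2
  kk <- se2 / (se2 + sg2)
  set.seed(seed)
  eps <- (w - m[, "mu"]) * kk +
    matrix(stats::rnorm(length(w)), nrow(w), ncol(w)) * sqrt(kk * sg2)
  inv(lr0 + eps)
}

#' @export
print.vc_change_summary <- function(x, ...) {
  cat("<vc_change_summary>", x$attribute, "| prior:", x$prior_form, "\n")
  cat(sprintf("  grand mean %% of historical: %.1f (95%% CrI %.1f, %.1f)\n",
              x$grand$mean, x$grand$q2.5, x$grand$q97.5))
  if (!is.null(x$groups)) {
    cat("  management classes:\n")
    print(x$groups, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

# ---- parameter recovery ------------------------------------------------------

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a dataset from the model graph
#' (`mode = "from_model"`), refits the calibration-change model, and reports
#' per-parameter bias, RMSE and 95\% credible-interval coverage of the true
#' generating values.
#'
#' @param gen_config a [generator_config()]; its `mode` should be
#'   `"from_model"` so the estimator is checked against the model's own
#'   generative assumptions.
#' @param attribute attribute to fit (must be in `gen_config$attributes`).
#' @param fit_cfg a [fit_config()]; replicate seeds are derived from its
#'   seed.
#' @param replicates number of simulated datasets (>= 2).
#' @param prior_form prior form for the latent historical predictors.
#' @param site_covariates site covariates entered in the regression (the
#'   generator's true regression uses scaled distance upstream).
#' @return a `vc_recovery`: `per_replicate` and aggregated `summary`
#'   data.frames.
#' @export
recovery_experiment <- function(gen_config, attribute = "nativeness",
                                fit_cfg = fit_config(chains = 2, adapt = 500,
                                                     burnin = 750,
                                                     iterations = 1250),
                                replicates = 10,
                                prior_form = "uniform",
                                site_covariates = "distance_upstream") {
  if (replicates < 2) stop("replicates must be >= 2", call. = FALSE)
  pp <- gen_config$params[[attribute]]
  season <- gen_config$registry[[attribute]]$scale == "proportion"
  truth <- c(a = pp$a, "b[1]" = pp$b,
              if (length(site_covariates)) stats::setNames(pp$c, "c[1]"),
              mu = pp$mu, if (season) c(gamma = pp$gamma))
  # single-element b/c monitors come back unindexed
  flat <- function(nm) sub("^(b|c)\\[1\\]$", "\\1", nm)
  names(truth) <- vapply(names(truth), flat, character(1))
  rows <- lapply(seq_len(replicates), function(rep) {
    gc <- gen_config
    gc$seed <- gen_config$seed + 1000L * rep
    dat <- simulate_survey(gc)
    model <- build_calibration_change_model(dat, attribute,
                                            prior_form = prior_form,
                                            site_covariates = site_covariates)
    fc <- fit_cfg; fc$seed <- gc$seed
    fit <- suppressWarnings(fit_model(model, fc))
    m <- as.matrix(fit$samples)
    do.call(rbind, lapply(names(truth), function(par) {
      x <- m[, par]
      data.frame(replicate = rep, parameter = par, truth = truth[[par]],
                 mean = mean(x), q2.5 = cri(x, 0.025), q97.5 = cri(x, 0.975),
                 covered = cri(x, 0.025) <= truth[[par]] &&
                   truth[[par]] <= cri(x, 0.975))
    }))
  })
  per_rep <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_rep, per_rep$parameter), function(d) {
    data.frame(parameter = d$parameter[1], truth = d$truth[1],
               bias = mean(d$mean - d$truth),
               rmse = sqrt(mean((d$mean - d$truth)^2)),
               coverage = mean(d$covered))
  }))
  structure(list(per_replicate = per_rep, summary = agg,
                 replicates = replicates),
            class = "vc_recovery")
}

#' @export
print.vc_recovery <- function(x, ...) {
  cat("<vc_recovery>", x$replicates, "replicates\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
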