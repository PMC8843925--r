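#' Informative priors over latent historical attribute values
#'
#' A categorical historical score constrains, but does not determine, the
#' quantitative value it summarised. Four prior forms reinterpret a score as
#' a distribution over that latent value:
#' \describe{
#'   \item{midpoint}{a point mass at the category midpoint - the common
#'     "best guess" conversion; a prior that admits no uncertainty.}
#'   \item{uniform}{flat over the range of values implied by the category.}
#'   \item{normal}{moments taken from a reference dataset (here, typically
#'     the contemporary survey), unrestricted support.}
#'   \item{truncated_normal}{the reference normal restricted to the
#'     category range.}
#' }
#' Location and spread are carried on the attribute's link scale (cloglog
#' for proportions, log for densities), matching the linear predictor the
#' latent value enters.
#'
#' @param form one of `"midpoint"`, `"uniform"`, `"normal"`,
#'   `"truncated_normal"`.
#' @param support numeric `c(lower, upper)` on the link scale (`-Inf`/`Inf`
#'   for unrestricted); for midpoint, a zero-width interval.
#' @param location,spread normal moments on the link scale (`NA` for forms
#'   without them).
#' @param link the link scale the parameters live on.
#' @param reference_source identifier of the dataset that supplied the
#'   moments, if any.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(form, support, location = NA_real_, spread = NA_real_,
                       link = "cloglog", reference_source = NULL) {
  form <- match.arg(form, c("midpoint", "uniform", "normal", "truncated_normal"))
  if (form == "midpoint" && support[1] != support[2]) {
    stop("midpoint prior must have zero-width support", call. = FALSE)
  }
  structure(list(form = form, support = support, location = location,
                 spread = spread, link = link,
                 reference_source = reference_source),
            class = "prior_spec")
}

# link-scale category support used by all spread-carrying prior forms
prior_support <- function(score, spec, p_floor = 5e-4, d_floor = 0.05) {
  if (spec$scale == "proportion") {
    b <- category_bounds(spec, score) / 100
    lo <- max(b[[1]], p_floor); hi <- min(b[[2]], 1 - p_floor)
    c(link_transform(lo, "cloglog"), link_transform(hi, "cloglog"))
  } else {
    b <- category_bounds(spec, score)
    if (b[[1]] == b[[2]]) b <- c(0, spec$zero_cap)
    c(log(max(b[[1]], d_floor)), log(b[[2]]))
  }
}

#' Category midpoint reinterpretation of a score
#'
#' The arithmetic midpoint of the scored category, in natural attribute
#' units. The degenerate "None" category keeps its literal value 0; the
#' open-ended top category uses the configured cap.
#'
#' @param score category code (densities) or grid percentage (composition).
#' @param spec an [attribute_spec()].
#' @return a single value in attribute units (stems/ha or percent).
#' @examples
#' reg <- attribute_registry()
#' midpoint_value(1, reg$medium_tree_density)  # 20 stems/ha
#' @export
midpoint_value <- function(score, spec) {
  category_midpoint(spec, score)
}

#' @rdname midpoint_value
#' @param p_floor,d_floor floors applied before link transforms (see
#'   [generator_config()]).
#' @return `midpoint_prior()`: a zero-width [prior_spec()] located at the
#'   link-transformed midpoint.
#' @export
midpoint_prior <- function(score, spec, p_floor = 5e-4, d_floor = 0.05) {
  m <- midpoint_value(score, spec)
  v <- if (spec$scale == "proportion") {
    link_transform(zero_adjust(m / 100, epsilon = p_floor), "cloglog")
  } else {
    log(max(m, d_floor))
  }
  prior_spec("midpoint", support = c(v, v),
             link = if (spec$scale == "proportion") "cloglog" else "log")
}

#' Uniform prior over the scored category
#'
#' Flat over the range of values implied by the category, optionally widened
#' into adjacent categories by an overlap fraction (a simple allowance for
#' misclassification; 0 by default, since overlapping ranges made little
#' difference in practice).
#'
#' @inheritParams midpoint_prior
#' @param overlap fraction of the category range added to each end (clipped
#'   to the attribute support).
#' @return a [prior_spec()] with uniform support on the link scale.
#' @export
uniform_prior <- function(score, spec, overlap = 0, p_floor = 5e-4,
                          d_floor = 0.05) {
  lk <- if (spec$scale == "proportion") "cloglog" else "log"
  if (overlap > 0) {
    b <- category_bounds(spec, score)
    if (b[[1]] == b[[2]] && spec$scale == "density") b <- c(0, spec$zero_cap)
    w <- overlap * (b[[2]] - b[[1]])
    lo <- max(b[[1]] - w, 0)
    hi <- b[[2]] + w
    if (spec$scale == "proportion") {
      hi <- min(hi, 100)
      supp <- c(link_transform(max(lo / 100, p_floor), "cloglog"),
                link_transform(min(hi / 100, 1 - p_floor), "cloglog"))
    } else {
      supp <- c(log(max(lo, d_floor)), log(hi))
    }
  } else {
    supp <- prior_support(score, spec, p_floor, d_floor)
  }
  prior_spec("uniform", support = supp, link = lk)
}

#' Normal prior from a reference dataset
#'
#' Location and spread are the mean and sample SD of the link-transformed
#' reference values (typically the contemporary survey's quantitative
#' values). Such a prior carries no category information; on its own it
#' pulls every latent historical value toward the reference distribution.
#'
#' @param reference numeric vector of reference values in natural units
#'   (proportions in (0,1) or densities; zeros must be adjusted first).
#' @param spec an [attribute_spec()].
#' @param reference_source label recorded in the returned spec.
#' @param on_link compute moments on the link scale (default) or on the
#'   natural scale.
#' @return a [prior_spec()] with unrestricted support.
#' @export
normal_prior <- function(reference, spec, reference_source = "reference",
                         on_link = TRUE, p_floor = 5e-4, d_floor = 0.05) {
  if (length(reference) < 2 || length(unique(reference)) < 2) {
    stop("normal prior needs >= 2 distinct reference values", call. = FALSE)
  }
  lk <- if (spec$scale == "proportion") "cloglog" else "log"
  vals <- if (on_link) {
    if (spec$scale == "proportion") {
      link_transform(zero_adjust(reference, epsilon = p_floor), "cloglog")
    } else {
      log(pmax(reference, d_floor))
    }
  } else {
    reference
  }
  prior_spec("normal", support = c(-Inf, Inf), location = mean(vals),
             spread = stats::sd(vals), link = lk,
             reference_source = reference_source)
}

#' @rdname normal_prior
#' @param score category code or grid percentage giving the truncation range.
#' @param p_floor,d_floor floors applied before link transforms.
#' @return `truncated_normal_prior()`: the reference normal truncated to the
#'   scored category's link-scale range.
#' @export
truncated_normal_prior <- function(score, reference, spec,
                                   reference_source = "reference",
                                   p_floor = 5e-4, d_floor = 0.05) {
  np <- normal_prior(reference, spec, reference_source,
                     p_floor = p_floor, d_floor = d_floor)
  supp <- prior_support(score, spec, p_floor, d_floor)
  mass <- stats::pnorm(supp[2], np$location, np$spread) -
    stats::pnorm(supp[1], np$location, np$spread)
  if (mass < 1e-12) {
    warning("scored category carries essentially no mass under the reference ",
            "normal; renormalising anyway", call. = FALSE)
  }
  prior_spec("truncated_normal", support = supp, location = np$location,
             spread = np$spread, link = np$link,
             reference_source = reference_source)
}

#' Draw from a prior specification
#'
#' Seeded, reproducible draws honouring the declared support. Truncated
#' normals are sampled by inverse-CDF, so every draw respects the bounds
#' exactly.
#'
#' @param prior a [prior_spec()].
#' @param n number of draws.
#' @param seed integer seed.
#' @return numeric draws on the prior's link scale.
#' @export
sample_prior <- function(prior, n, seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  switch(prior$form,
    midpoint = rep(prior$support[1], n),
    uniform = stats::runif(n, prior$support[1], prior$support[2]),
    normal = stats::rnorm(n, prior$location, prior$spread),
    truncated_normal = {
      plo <- stats::pnorm(prior$support[1], prior$location, prior$spread)
      phi <- stats::pnorm(prior$support[2], prior$location, prior$spread)
      u <- stats::runif(n, plo, phi)
      stats::qnorm(u, prior$location, prior$spread)
    }
  )
}

#' Closed-form mean of a truncated normal prior
#'
#' The analytic mean of a `truncated_normal` [prior_spec()], used as an
#' independent oracle for its sampler.
#'
#' @param prior a truncated-normal [prior_spec()].
#' @return the mean on the link scale.
#' @export
truncated_normal_mean <- function(prior) {
  stopifnot(prior$form == "truncated_normal")
  a <- (prior$support[1] - prior$location) / prior$spread
  b <- (prior$support[2] - prior$location) / prior$spread
  z <- stats::pnorm(b) - stats::pnorm(a)
  prior$location + prior$spread * (stats::dnorm(a) - stats::dnorm(b)) / z
}
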