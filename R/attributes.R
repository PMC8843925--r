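#' Define a scoring category for a density attribute
#'
#' A category is a half-open interval of attribute values with an ordinal
#' code. The "None" category of tree-density scores is the single point
#' \{0\}: a score of zero trees is a count of zero, not a range. The top,
#' open-ended category ("Much") must be closed with an explicit cap before it
#' can be used by midpoint or uniform prior constructions.
#'
#' @param label category name as printed on the field sheet.
#' @param lower inclusive lower bound, in attribute units.
#' @param upper exclusive upper bound, or `Inf` for an open-ended category.
#' @param code ordinal integer code, consecutive from 0.
#' @return an object of class `category_def`.
#' @export
category_def <- function(label, lower, upper, code) {
  if (lower > upper) stop("category lower bound exceeds upper bound", call. = FALSE)
  structure(list(label = label, lower = lower, upper = upper, code = as.integer(code)),
            class = "category_def")
}

#' Attribute specification
#'
#' Couples an attribute's measurement scale to its likelihood family and its
#' historical scoring system. Proportion attributes (understorey nativeness)
#' are binomial with a cloglog link; density attributes (stems per hectare)
#' are Poisson with a log link.
#'
#' @param name one of `"nativeness"`, `"recruit_density"`,
#'   `"medium_tree_density"`.
#' @param scale `"proportion"` or `"density"`.
#' @param family `"binomial_cloglog"` or `"poisson_log"`.
#' @param categories list of [category_def()] for density attributes; `NULL`
#'   for composition-scored attributes.
#' @param composition for nativeness: the labels of the four composition
#'   parts, each scored to the nearest `resolution` percent and summing to
#'   100.
#' @param resolution scoring resolution of composition parts, in percent.
#' @param open_end_cap configured upper bound (attribute units) closing the
#'   open-ended top category.
#' @param zero_cap upper bound of the support used by spread-carrying priors
#'   for the degenerate "None" category (see Details).
#' @details `zero_cap` exists because the "None" category is the point \{0\}:
#'   a point carries no interval for a uniform or truncated-normal prior. For
#'   those prior forms only, "None" is read as "below detection", i.e. the
#'   interval (0, `zero_cap`]. The midpoint reading of "None" stays exactly 0.
#' @return an object of class `attribute_spec`.
#' @export
attribute_spec <- function(name, scale, family, categories = NULL,
                           composition = NULL, resolution = 5,
                           open_end_cap = NULL, zero_cap = 1) {
  scale <- match.arg(scale, c("proportion", "density"))
  family <- match.arg(family, c("binomial_cloglog", "poisson_log"))
  if (scale == "proportion" && family != "binomial_cloglog") {
    stop("proportion attributes use the binomial_cloglog family", call. = FALSE)
  }
  if (scale == "density" && family != "poisson_log") {
    stop("density attributes use the poisson_log family", call. = FALSE)
  }
  if (!is.null(categories)) {
    codes <- vapply(categories, `[[`, integer(1), "code")
    if (!identical(codes, seq_along(codes) - 1L)) {
      stop("category codes must be consecutive from 0", call. = FALSE)
    }
    top <- categories[[length(categories)]]
    if (is.infinite(top$upper) && is.null(open_end_cap)) {
      stop("open-ended top category requires a configured `open_end_cap`",
           call. = FALSE)
    }
    if (!is.null(open_end_cap) && open_end_cap <= top$lower) {
      stop("`open_end_cap` must exceed the highest finite category boundary",
           call. = FALSE)
    }
  }
  structure(list(name = name, scale = scale, family = family,
                 categories = categories, composition = composition,
                 resolution = resolution, open_end_cap = open_end_cap,
                 zero_cap = zero_cap),
            class = "attribute_spec")
}

#' The three-attribute registry
#'
#' Builds the attribute registry used throughout: understorey nativeness
#' (four composition parts scored to the nearest 5%, summing to 100%),
#' tree recruitment density (None / Some < 50 per ha / Much > 50 per ha) and
#' medium tree density (None / Some < 40 per ha / Much > 40 per ha). The
#' open-ended "Much" categories have no stated upper bound, so a cap must be
#' supplied; the default is ten times the finite boundary.
#'
#' @param open_end_caps named numeric vector of caps (stems/ha) for the
#'   open-ended categories of the density attributes.
#' @param zero_caps named numeric vector of detection-floor caps for the
#'   "None" categories (see [attribute_spec()]).
#' @return named list of three [attribute_spec()] objects.
#' @examples
#' reg <- attribute_registry()
#' category_bounds(reg$medium_tree_density, 1)   # (0, 40)
#' @export
attribute_registry <- function(open_end_caps = c(recruit_density = 500,
                                                 medium_tree_density = 400),
                               zero_caps = c(recruit_density = 1,
                                             medium_tree_density = 1)) {
  dens <- function(nm, threshold) {
    if (!nm %in% names(open_end_caps) || is.na(open_end_caps[[nm]])) {
      stop("missing open_end_cap for attribute ", nm, call. = FALSE)
    }
    cap <- open_end_caps[[nm]]
    if (!nm %in% names(zero_caps)) {
      stop("missing zero_cap for attribute ", nm, call. = FALSE)
    }
    attribute_spec(
      name = nm, scale = "density", family = "poisson_log",
      categories = list(
        category_def("None", 0, 0, 0),
        category_def("Some", 0, threshold, 1),
        category_def("Much", threshold, Inf, 2)
      ),
      open_end_cap = cap, zero_cap = zero_caps[[nm]]
    )
  }
  list(
    nativeness = attribute_spec(
      name = "nativeness", scale = "proportion", family = "binomial_cloglog",
      composition = c("mostly_native", "mostly_weedy", "fifty_fifty", "bare"),
      resolution = 5
    ),
    recruit_density = dens("recruit_density", 50),
    medium_tree_density = dens("medium_tree_density", 40)
  )
}

#' Category bounds and midpoints
#'
#' For density attributes, `score` is the ordinal category code and the
#' bounds are the category interval (the open-ended top category is closed by
#' the configured cap). For composition attributes, `score` is a percentage
#' on the scoring grid and the bounds are the half-resolution window around
#' it, clipped to \[0, 100\].
#'
#' @param spec an [attribute_spec()].
#' @param score ordinal code (density) or percentage (composition).
#' @return `category_bounds()`: numeric vector `c(lower, upper)` in attribute
#'   units; `category_midpoint()`: a single value.
#' @export
category_bounds <- function(spec, score) {
  if (!is.null(spec$categories)) {
    cat <- category_lookup(spec, score)
    up <- if (is.infinite(cat$upper)) spec$open_end_cap else cat$upper
    return(c(lower = cat$lower, upper = up))
  }
  half <- spec$resolution / 2
  if (any(score < 0 | score > 100)) stop("composition score outside [0, 100]", call. = FALSE)
  c(lower = max(score - half, 0), upper = min(score + half, 100))
}

#' @rdname category_bounds
#' @export
category_midpoint <- function(spec, score) {
  b <- category_bounds(spec, score)
  unname((b[1] + b[2]) / 2)
}

category_lookup <- function(spec, score) {
  codes <- vapply(spec$categories, `[[`, integer(1), "code")
  i <- match(as.integer(score), codes)
  if (any(is.na(i))) {
    stop("invalid category code ", paste(score[is.na(i)], collapse = ", "),
         " for attribute ", spec$name, call. = FALSE)
  }
  spec$categories[[i]]
}

#' Score a true attribute value on the historical categorical scale
#'
#' Density values are thresholded into the registry categories ("None" is
#' exactly zero). Composition values are rounded to the scoring grid.
#'
#' @param spec an [attribute_spec()].
#' @param value attribute value(s) in natural units.
#' @return integer category code(s) or grid percentage(s).
#' @export
score_value <- function(spec, value) {
  if (!is.null(spec$categories)) {
    if (any(value < 0)) stop("negative density", call. = FALSE)
    ups <- vapply(spec$categories, `[[`, numeric(1), "upper")
    thresholds <- ups[is.finite(ups) & ups > 0]  # e.g. 40 or 50 stems/ha
    out <- rep(0L, length(value))
    pos <- value > 0
    # positive values: 1 + number of thresholds met (ties go up)
    out[pos] <- 1L + vapply(value[pos], function(v) sum(v >= thresholds), integer(1))
    return(out)
  }
  round(value / spec$resolution) * spec$resolution
}

#' Centre and scale continuous predictors
#'
#' Continuous site predictors are centred and divided by two standard
#' deviations, so a binary predictor and a scaled continuous predictor have
#' coefficients on a comparable scale and MCMC chains mix better. Binary
#' predictors are left untouched. The returned scaling record reapplies the
#' identical transformation to new data.
#'
#' @param data a data.frame.
#' @param columns character vector of continuous columns to scale.
#' @param scaling a scaling record from a previous call, to reapply.
#' @return `scale_predictors()`: list with `data` (scaled data.frame) and
#'   `scaling` (named list of `center`/`scale` per column).
#'   `unscale_predictors()` reverses the transformation.
#' @examples
#' s <- scale_predictors(data.frame(x = 1:4), "x")
#' colMeans(s$data)           # 0
#' sd(s$data$x)               # 0.5
#' @export
scale_predictors <- function(data, columns, scaling = NULL) {
  if (is.null(scaling)) {
    scaling <- lapply(columns, function(cl) {
      x <- data[[cl]]
      if (length(unique(x)) < 2) {
        stop("predictor `", cl, "` is constant; cannot scale", call. = FALSE)
      }
      list(center = mean(x), scale = 2 * stats::sd(x))
    })
    names(scaling) <- columns
  }
  for (cl in names(scaling)) {
    data[[cl]] <- (data[[cl]] - scaling[[cl]]$center) / scaling[[cl]]$scale
  }
  list(data = data, scaling = scaling)
}

#' @rdname scale_predictors
#' @export
unscale_predictors <- function(data, scaling) {
  for (cl in names(scaling)) {
    data[[cl]] <- data[[cl]] * scaling[[cl]]$scale + scaling[[cl]]$center
  }
  data
}

management_class_table <- function() {
  data.frame(
    licence_t1 = c(0, 1, 1, 1, 1),
    fence_t1   = c(1, 1, 0, 0, 0),
    licence_t2 = c(0, 0, 0, 1, 1),
    fence_t2   = c(1, 1, 1, 1, 0),
    class = c("No licence, fence", "Revoke licence, fence",
              "Revoke licence, install fence", "Licence, install fence",
              "Licence, no fence"),
    changed = c(FALSE, TRUE, TRUE, TRUE, FALSE)
  )
}

#' Assign grazing-management transition classes
#'
#' Maps a site's licenced/fenced status at the two survey periods to one of
#' the five named management transitions (two unchanged, three changed);
#' combinations outside the five named ones return `"other"`.
#'
#' @param licence_t1,fence_t1,licence_t2,fence_t2 binary (0/1) management
#'   indicators at the historical (t1) and contemporary (t2) surveys.
#'   Alternatively, pass a data.frame with these columns as the first
#'   argument.
#' @return character vector of class labels.
#' @examples
#' assign_management_class(1, 1, 0, 1)  # "Revoke licence, fence"
#' @export
assign_management_class <- function(licence_t1, fence_t1 = NULL,
                                    licence_t2 = NULL, fence_t2 = NULL) {
  if (is.data.frame(licence_t1)) {
    df <- licence_t1
    licence_t1 <- df$licence_t1; fence_t1 <- df$fence_t1
    licence_t2 <- df$licence_t2; fence_t2 <- df$fence_t2
  }
  stopifnot(!is.null(fence_t1), !is.null(licence_t2), !is.null(fence_t2))
  tab <- management_class_table()
  key <- paste(licence_t1, fence_t1, licence_t2, fence_t2)
  tabkey <- paste(tab$licence_t1, tab$fence_t1, tab$licence_t2, tab$fence_t2)
  out <- tab$class[match(key, tabkey)]
  out[is.na(out)] <- "other"
  out
}
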