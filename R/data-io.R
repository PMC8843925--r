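#' Survey dataset container and CSV input/output
#'
#' A survey dataset links four tables by `site_id`:
#' \describe{
#'   \item{sites}{one row per site: `site_id`, `distance_upstream` (km),
#'     `creek`, `area` (ha), binaries `road`, `cropping`, `grazing`, `water`,
#'     `days_offset` (day-of-year difference between the two surveys of the
#'     site), and the management binaries `licence_t1`, `fence_t1`,
#'     `licence_t2`, `fence_t2`.}
#'   \item{historical}{categorical scores per site and attribute: either an
#'     ordinal `score` (densities) or the four composition parts
#'     `mostly_native`, `mostly_weedy`, `fifty_fifty`, `bare` (percent,
#'     multiples of the scoring resolution, summing to 100).}
#'   \item{contemporary}{quantitative responses: `hits` from `points`
#'     (proportion attributes) or `count` with `sampled_area` in ha (density
#'     attributes).}
#'   \item{calibration}{double-sampled pairs: for a subset of contemporary
#'     sites, a historical-method score collected contemporaneously
#'     (same columns as `historical` plus `offset_days`, the days between the
#'     paired surveys) alongside the site's contemporary observation.}
#' }
#'
#' @param sites,historical,contemporary,calibration data.frames as described.
#' @param validate validate referential integrity and value constraints.
#' @return an object of class `survey_data`.
#' @export
survey_data <- function(sites, historical, contemporary, calibration = NULL,
                        validate = TRUE) {
  x <- structure(list(sites = sites, historical = historical,
                      contemporary = contemporary, calibration = calibration),
                 class = "survey_data")
  if (validate) validate_survey_data(x)
  x
}

#' @rdname survey_data
#' @param x a `survey_data` object.
#' @export
validate_survey_data <- function(x) {
  st <- x$sites
  req <- c("site_id", "days_offset")
  miss <- setdiff(req, names(st))
  if (length(miss)) stop("sites table missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (anyDuplicated(st$site_id)) stop("duplicate site_id in sites table", call. = FALSE)
  if (!is.null(st$area) && any(st$area <= 0)) stop("site area must be > 0", call. = FALSE)

  check_sites <- function(tab, nm) {
    bad <- which(!(tab$site_id %in% st$site_id))
    if (length(bad)) {
      stop(nm, " row ", bad[1], ": unknown site_id `", tab$site_id[bad[1]], "`",
           call. = FALSE)
    }
  }
  check_comp <- function(tab, nm) {
    parts <- c("mostly_native", "mostly_weedy", "fifty_fifty", "bare")
    if (all(parts %in% names(tab))) {
      rows <- tab$attribute == "nativeness"
      tot <- rowSums(tab[rows, parts, drop = FALSE])
      bad <- which(abs(tot - 100) > 1e-8)
      if (length(bad)) {
        stop(nm, " row ", which(rows)[bad[1]], ": composition parts sum to ",
             tot[bad[1]], ", not 100", call. = FALSE)
      }
    }
  }
  check_sites(x$historical, "historical"); check_comp(x$historical, "historical")
  ct <- x$contemporary
  check_sites(ct, "contemporary")
  if ("hits" %in% names(ct)) {
    rows <- which(!is.na(ct$hits))
    bad <- rows[ct$hits[rows] > ct$points[rows] | ct$hits[rows] < 0]
    if (length(bad)) {
      stop("contemporary row ", bad[1], ": hits (", ct$hits[bad[1]],
           ") outside [0, points = ", ct$points[bad[1]], "]", call. = FALSE)
    }
    if (any(ct$points[rows] <= 0)) stop("points must be > 0", call. = FALSE)
  }
  if ("sampled_area" %in% names(ct)) {
    rows <- which(!is.na(ct$sampled_area))
    if (any(ct$sampled_area[rows] <= 0)) stop("sampled_area must be > 0", call. = FALSE)
  }
  if (!is.null(x$calibration)) {
    check_sites(x$calibration, "calibration"); check_comp(x$calibration, "calibration")
    if ("offset_days" %in% names(x$calibration)) {
      bad <- which(abs(x$calibration$offset_days) > 14)
      if (length(bad)) {
        stop("calibration row ", bad[1], ": paired surveys ",
             x$calibration$offset_days[bad[1]], " days apart (limit 14)",
             call. = FALSE)
      }
    }
  }
  invisible(x)
}

#' @rdname survey_data
#' @param dir directory holding `sites.csv`, `historical.csv`,
#'   `contemporary.csv` and optionally `calibration.csv` (and `truth.csv`
#'   from the synthetic generator).
#' @export
read_survey_data <- function(dir, validate = TRUE) {
  int_cols <- c("score", "hits", "points", "count", "days_offset",
                "offset_days")
  num_cols <- c("sampled_area", "mostly_native", "mostly_weedy",
                "fifty_fifty", "bare")
  rd <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) return(NULL)
    tab <- utils::read.csv(p, stringsAsFactors = FALSE)
    for (cl in intersect(int_cols, names(tab))) tab[[cl]] <- as.integer(tab[[cl]])
    for (cl in intersect(num_cols, names(tab))) tab[[cl]] <- as.numeric(tab[[cl]])
    tab
  }
  sites <- rd("sites.csv")
  if (is.null(sites)) stop("no sites.csv in ", dir, call. = FALSE)
  x <- survey_data(sites, rd("historical.csv"), rd("contemporary.csv"),
                   rd("calibration.csv"), validate = validate)
  x$truth <- rd("truth.csv")
  x
}

#' @rdname survey_data
#' @export
write_survey_data <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(tab, f) {
    if (!is.null(tab)) utils::write.csv(tab, file.path(dir, f), row.names = FALSE)
  }
  wr(x$sites, "sites.csv"); wr(x$historical, "historical.csv")
  wr(x$contemporary, "contemporary.csv"); wr(x$calibration, "calibration.csv")
  wr(x$truth, "truth.csv")
  invisible(dir)
}

#' @export
print.survey_data <- function(x, ...) {
  cat("<survey_data>\n")
  cat("  sites:        ", nrow(x$sites), "\n")
  cat("  historical:   ", if (is.null(x$historical)) 0 else nrow(x$historical), "rows\n")
  cat("  contemporary: ", if (is.null(x$contemporary)) 0 else nrow(x$contemporary), "rows\n")
  cat("  calibration:  ", if (is.null(x$calibration)) 0 else nrow(x$calibration), "rows\n")
  invisible(x)
}
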