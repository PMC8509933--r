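#' Per-unit residuals from a scaling fit
#'
#' Residuals are observed minus fitted on the log scale; standardized
#' residuals divide by the fit's residual SD (degrees-of-freedom
#' corrected). The record set carries the unit population so diagnostics
#' can be plotted against size, and an `outlier` flag (all FALSE until
#' [flag_outliers()]).
#'
#' @param data the log-log dataset the fit was estimated on.
#' @param fit a `scaling_fit` produced on `data`.
#' @return data.frame with columns `unit_id`, `population`, `residual`,
#'   `std_residual`, `outlier`, `outlier_sign`.
#' @export
compute_residuals <- function(data, fit) {
  stopifnot(inherits(fit, "scaling_fit"))
  check_loglog(data)
  if (!setequal(data$unit_id, fit$unit_id) || nrow(data) != fit$n) {
    stop("fit was not produced on this dataset (unit set mismatch)",
         call. = FALSE)
  }
  r <- unname(fit$residuals[data$unit_id])
  data.frame(
    unit_id = data$unit_id,
    population = exp(data$x),
    residual = r,
    std_residual = r / fit$sigma,
    outlier = FALSE,
    outlier_sign = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Flag outlying units by standardized residual
#'
#' Default rule: |standardized residual| >= 3, with the sign reported so
#' negative (lower-than-expected) and positive outliers are separately
#' countable.
#'
#' @param records residual records from [compute_residuals()].
#' @param threshold positive threshold in SD units (default 3).
#' @return `records` with `outlier` and `outlier_sign` filled.
#' @export
flag_outliers <- function(records, threshold = 3) {
  stopifnot(is.data.frame(records), "std_residual" %in% names(records),
            is.numeric(threshold), threshold > 0)
  z <- records$std_residual
  records$outlier <- abs(z) >= threshold
  records$outlier_sign <- ifelse(!records$outlier, NA_character_,
                                 ifelse(z < 0, "negative", "positive"))
  records
}

#' Refit the two-regime model after excluding units
#'
#' Sensitivity analysis around influential observations: drop the given
#' units and refit either (a) with the knot held at its original value, or
#' (b) re-running the knot search on the reduced data. With an empty
#' exclusion set and fixed knot the result is identical to the original
#' fit.
#'
#' @param data log-log dataset.
#' @param exclude character vector of unit_ids to drop (may be empty).
#' @param knot the knot population: held fixed when `mode = "fixed"`,
#'   ignored when `mode = "search"`.
#' @param mode `"fixed"` or `"search"`.
#' @param covariates optional covariate columns.
#' @return list of class `rerun_result`: `fit`, `knot`, `knot_percentile`
#'   (of the knot within the retained populations), `mode`, `excluded`,
#'   and `profile` (search mode only).
#' @export
rerun_excluding <- function(data, exclude = character(0), knot = NULL,
                            mode = c("fixed", "search"), covariates = NULL) {
  mode <- match.arg(mode)
  check_loglog(data, covariates)
  unknown <- setdiff(exclude, data$unit_id)
  if (length(unknown)) {
    stop(sprintf("excluded unit(s) not in data: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  kept <- data[!(data$unit_id %in% exclude), , drop = FALSE]
  if (mode == "fixed") {
    stopifnot(is.numeric(knot), length(knot) == 1)
    fit <- fit_piecewise(kept, knot, covariates = covariates)
    out <- list(fit = fit, knot = knot,
                knot_percentile = percentile_of(knot, exp(kept$x)),
                mode = mode, excluded = exclude, profile = NULL)
  } else {
    ks <- search_knot(kept, covariates = covariates)
    out <- list(fit = ks$fit, knot = ks$knot,
                knot_percentile = percentile_of(ks$knot, exp(kept$x)),
                mode = mode, excluded = exclude, profile = ks$profile)
  }
  structure(out, class = "rerun_result")
}

#' Loess smoother of standardized residuals on log-population
#'
#' The diagnostic that exposes non-linear scaling: a locally weighted
#' regression of standardized residuals on ln(population), evaluated on an
#' even grid spanning the observed range. A U-shaped curve indicates a
#' single exponent is misspecified across the size range.
#'
#' @param records residual records from [compute_residuals()].
#' @param span loess span in (0, 1] (default 0.75).
#' @param n_grid number of evaluation points (>= 100).
#' @return data.frame of class `smoother_curve` with columns `log_pop` and
#'   `smoothed`; the span is attached as an attribute.
#' @export
smooth_std_residuals <- function(records, span = 0.75, n_grid = 101) {
  stopifnot(is.data.frame(records),
            all(c("population", "std_residual") %in% names(records)))
  if (nrow(records) < 10) stop("need at least 10 records", call. = FALSE)
  if (!is.numeric(span) || span <= 0 || span > 1) {
    stop("span must be in (0, 1]", call. = FALSE)
  }
  n_grid <- max(100L, as.integer(n_grid))
  lx <- log(records$population)
  lo <- suppressWarnings(
    stats::loess(records$std_residual ~ lx, span = span, degree = 2,
                 family = "gaussian")
  )
  grid <- seq(min(lx), max(lx), length.out = n_grid)
  curve <- data.frame(log_pop = grid,
                      smoothed = unname(stats::predict(lo, newdata = data.frame(lx = grid))))
  attr(curve, "span") <- span
  class(curve) <- c("smoother_curve", "data.frame")
  curve
}

#' Export residual records as a GeoJSON feature collection
#'
#' Joins residual records to unit polygons and writes an RFC 7946 GeoJSON
#' FeatureCollection with `residual`, `std_residual` and `outlier`
#' properties per unit, ready for choropleth mapping in any GIS tool.
#' Records without a geometry are skipped (reported via the return value
#' and a message); a malformed geometry is a hard error naming the unit.
#'
#' @param records residual records from [compute_residuals()].
#' @param geometry named list (by unit_id) of polygon rings: each element
#'   a numeric matrix of lon/lat with >= 4 rows, closed (first row equals
#'   last), or a list of such rings (outer ring first).
#' @param path output path (.geojson).
#' @return invisibly, a list with `path`, `n_written`, `skipped` (unit_ids
#'   lacking geometry).
#' @export
export_residual_geo <- function(records, geometry, path) {
  stopifnot(is.data.frame(records), is.list(geometry))
  check_ring <- function(ring, id) {
    if (!is.matrix(ring) || !is.numeric(ring) || ncol(ring) != 2 ||
        nrow(ring) < 4 || anyNA(ring) ||
        !isTRUE(all.equal(ring[1, ], ring[nrow(ring), ]))) {
      stop(sprintf("malformed geometry for unit %s", id), call. = FALSE)
    }
    ring
  }
  skipped <- character(0)
  features <- list()
  for (i in seq_len(nrow(records))) {
    id <- records$unit_id[[i]]
    geom <- geometry[[id]]
    if (is.null(geom)) {
      skipped <- c(skipped, id)
      next
    }
    rings <- if (is.matrix(geom)) list(geom) else geom
    rings <- lapply(rings, check_ring, id = id)
    features[[length(features) + 1]] <- list(
      type = "Feature",
      properties = list(
        unit_id = id,
        population = records$population[[i]],
        residual = records$residual[[i]],
        std_residual = records$std_residual[[i]],
        outlier = isTRUE(records$outlier[[i]])
      ),
      geometry = list(type = "Polygon", coordinates = rings)
    )
  }
  if (length(skipped)) {
    message(sprintf("no geometry for %d unit(s): %s", length(skipped),
                    paste(utils::head(skipped, 10), collapse = ", ")))
  }
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(list(path = path, n_written = length(features),
                 skipped = skipped))
}
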