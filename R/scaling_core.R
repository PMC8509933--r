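#' Build a log-log dataset from a unit table
#'
#' Takes natural logs of the unit pill total (response) and mean population
#' (predictor). Units with a non-positive pill total or population cannot
#' enter a log-log fit and are dropped with a warning naming them.
#'
#' @param units unit table (see [aggregate_to_units()]).
#' @return data.frame with columns `unit_id`, `x` (= ln population),
#'   `y` (= ln pills), `population`, plus `region`/`stratum` and any other
#'   columns carried through for use as covariates or strata.
#' @export
log_log_data <- function(units) {
  stopifnot(is.data.frame(units),
            all(c("unit_id", "pills_total", "pop_mean") %in% names(units)))
  bad <- units$pills_total <= 0 | units$pop_mean <= 0 |
    !is.finite(units$pills_total) | !is.finite(units$pop_mean)
  if (any(bad)) {
    warning(sprintf("dropping %d unit(s) with non-positive counts: %s",
                    sum(bad),
                    paste(utils::head(units$unit_id[bad], 10), collapse = ", ")),
            call. = FALSE)
    units <- units[!bad, , drop = FALSE]
  }
  extra <- setdiff(names(units), c("unit_id", "pills_total", "pop_mean"))
  out <- data.frame(unit_id = as.character(units$unit_id),
                    x = log(units$pop_mean),
                    y = log(units$pills_total),
                    population = units$pop_mean,
                    stringsAsFactors = FALSE)
  for (col in extra) out[[col]] <- units[[col]]
  rownames(out) <- NULL
  out
}

#' @keywords internal
check_loglog <- function(data, covariates = NULL) {
  stopifnot(is.data.frame(data), all(c("unit_id", "x", "y") %in% names(data)))
  if (!all(is.finite(data$x)) || !all(is.finite(data$y))) {
    stop("non-finite values in log-log data", call. = FALSE)
  }
  miss <- setdiff(covariates, names(data))
  if (length(miss)) {
    stop(sprintf("covariate column(s) not in data: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(data)
}

#' @keywords internal
lm_rank_check <- function(fit) {
  if (fit$rank < length(coef(fit)) || anyNA(coef(fit))) {
    stop("rank-deficient design matrix", call. = FALSE)
  }
  fit
}

#' @keywords internal
covariate_coef_extract <- function(fit, covariates) {
  if (is.null(covariates) || !length(covariates)) return(NULL)
  cf <- coef(fit)
  keep <- setdiff(names(cf), c("(Intercept)", "x", ".hinge"))
  cf[keep]
}

#' Fit the single-regime power-law scaling model
#'
#' Ordinary least squares for ln(Y) = alpha + beta ln(N) + eps, the standard
#' urban-scaling regression; beta is the scaling exponent (elasticity of the
#' outcome with respect to population). Optional covariates enter additively
#' on the log scale (character/factor columns expand to dummies).
#'
#' @param data log-log dataset from [log_log_data()].
#' @param covariates optional character vector of covariate column names.
#' @return Object of class `power_law_fit`: list with `alpha`, `beta`,
#'   `beta_ci` (95% t-interval), `sigma` (residual SD, df-corrected),
#'   `loglik` (maximized Gaussian log-likelihood, constants included),
#'   `aic` (= -2 loglik + 2k, k counting intercept, slope, covariates and
#'   sigma), `n`, `covariate_coefs`, plus the residuals/fitted values and
#'   coefficient covariance needed downstream.
#' @examples
#' d <- data.frame(unit_id = letters[1:10], x = 1:10, y = 2 + 1:10)
#' f <- fit_power_law(d)
#' c(f$alpha, f$beta)  # 2, 1
#' @export
fit_power_law <- function(data, covariates = NULL) {
  check_loglog(data, covariates)
  if (nrow(data) < 3) stop("need at least 3 points", call. = FALSE)
  form <- stats::reformulate(c("x", covariates), response = "y")
  fit <- lm_rank_check(stats::lm(form, data = data))
  ci <- stats::confint(fit, "x", level = 0.95)
  structure(list(
    alpha = unname(coef(fit)[["(Intercept)"]]),
    beta = unname(coef(fit)[["x"]]),
    beta_ci = c(ci[1, 1], ci[1, 2]),
    sigma = summary(fit)$sigma,
    loglik = as.numeric(stats::logLik(fit)),
    aic = stats::AIC(fit),
    n = nrow(data),
    df_residual = fit$df.residual,
    covariate_coefs = covariate_coef_extract(fit, covariates),
    covariates = covariates,
    coefficients = coef(fit),
    vcov = stats::vcov(fit),
    fitted = stats::setNames(unname(stats::fitted(fit)), data$unit_id),
    residuals = stats::setNames(unname(stats::residuals(fit)), data$unit_id),
    unit_id = data$unit_id,
    model = "power_law"
  ), class = c("power_law_fit", "scaling_fit"))
}

#' Fit the continuous two-regime (single-knot) power-law model
#'
#' OLS on the continuous hinge basis {1, ln N, (ln N - ln k) 1\[N > k\]}:
#' `beta1` is the scaling exponent below the knot, `beta2 = beta1 + gamma`
#' (gamma the hinge coefficient) the exponent above it, and the fitted mean
#' is continuous at ln(k) by construction. Points with population exactly
#' equal to the knot belong to the below-knot side. The 95% interval for
#' `beta2` uses the variance of the linear combination beta1 + gamma from
#' the coefficient covariance matrix.
#'
#' @inheritParams fit_power_law
#' @param knot knot position as a population value (natural scale, persons).
#' @return Object of class `piecewise_fit`: list with `alpha`, `beta1`,
#'   `beta2`, `knot`, `beta1_ci`, `beta2_ci`, `sigma`, `loglik`, `aic`,
#'   `n`, `n_below`, `n_above`, `covariate_coefs` and fit internals.
#' @export
fit_piecewise <- function(data, knot, covariates = NULL) {
  check_loglog(data, covariates)
  stopifnot(is.numeric(knot), length(knot) == 1, knot > 0)
  lk <- log(knot)
  n_below <- sum(data$x <= lk)
  n_above <- sum(data$x > lk)
  if (sum(data$x < lk) < 2 || n_above < 2) {
    stop(sprintf(
      "knot %g leaves fewer than 2 points strictly on one side", knot
    ), call. = FALSE)
  }
  if (nrow(data) < 5) stop("need at least 5 points", call. = FALSE)
  data$.hinge <- ifelse(data$x > lk, data$x - lk, 0)
  form <- stats::reformulate(c("x", ".hinge", covariates), response = "y")
  fit <- lm_rank_check(stats::lm(form, data = data))
  cf <- coef(fit)
  V <- stats::vcov(fit)
  beta1 <- unname(cf[["x"]])
  gamma <- unname(cf[[".hinge"]])
  beta2 <- beta1 + gamma
  se1 <- sqrt(V["x", "x"])
  se2 <- sqrt(V["x", "x"] + V[".hinge", ".hinge"] + 2 * V["x", ".hinge"])
  tq <- stats::qt(0.975, fit$df.residual)
  structure(list(
    alpha = unname(cf[["(Intercept)"]]),
    beta1 = beta1,
    beta2 = beta2,
    knot = knot,
    beta1_ci = c(beta1 - tq * se1, beta1 + tq * se1),
    beta2_ci = c(beta2 - tq * se2, beta2 + tq * se2),
    hinge_coef = gamma,
    hinge_ci = c(gamma - tq * sqrt(V[".hinge", ".hinge"]),
                 gamma + tq * sqrt(V[".hinge", ".hinge"])),
    sigma = summary(fit)$sigma,
    loglik = as.numeric(stats::logLik(fit)),
    aic = stats::AIC(fit),
    n = nrow(data),
    n_below = n_below,
    n_above = n_above,
    df_residual = fit$df.residual,
    covariate_coefs = covariate_coef_extract(fit, covariates),
    covariates = covariates,
    coefficients = cf,
    vcov = V,
    fitted = stats::setNames(unname(stats::fitted(fit)), data$unit_id),
    residuals = stats::setNames(unname(stats::residuals(fit)), data$unit_id),
    unit_id = data$unit_id,
    model = "piecewise"
  ), class = c("piecewise_fit", "scaling_fit"))
}

#' Exhaustive profile-likelihood search for the knot position
#'
#' Evaluates the two-regime model at every candidate knot and returns the
#' candidate maximizing the Gaussian log-likelihood (equivalently minimizing
#' the residual sum of squares); ties break toward the smallest knot. The
#' default candidate grid is every observed population strictly between the
#' 5th and 95th population percentiles — exhaustive over observed values,
#' which is exact at the scale of a few hundred units and avoids the
#' convergence ambiguity of iterative breakpoint searches.
#'
#' @inheritParams fit_power_law
#' @param candidates optional numeric vector of candidate knots
#'   (population values); default derived from `grid_quantiles`.
#' @param grid_quantiles lower/upper population quantiles bounding the
#'   default grid (default `c(0.05, 0.95)`).
#' @return List of class `knot_search`: `knot` (selected), `fit` (the
#'   [fit_piecewise()] result at it), and `profile`, a data.frame of
#'   candidate knot, log-likelihood and RSS for diagnostics.
#' @export
search_knot <- function(data, covariates = NULL, candidates = NULL,
                        grid_quantiles = c(0.05, 0.95)) {
  check_loglog(data, covariates)
  if (nrow(data) < 5) stop("need at least 5 points", call. = FALSE)
  pop <- exp(data$x)
  if (is.null(candidates)) {
    qs <- stats::quantile(pop, grid_quantiles, names = FALSE, type = 7)
    candidates <- sort(unique(pop[pop > qs[1] & pop < qs[2]]))
  } else {
    candidates <- sort(unique(candidates))
  }
  # feasibility: >= 2 points strictly on each side
  lx <- log(candidates)
  ok <- vapply(lx, function(l) {
    sum(data$x < l) >= 2 && sum(data$x > l) >= 2
  }, logical(1))
  candidates <- candidates[ok]
  if (!length(candidates)) {
    stop("no feasible candidate knots after trimming", call. = FALSE)
  }

  X0 <- cbind(`(Intercept)` = 1, x = data$x)
  if (!is.null(covariates) && length(covariates)) {
    mm <- stats::model.matrix(
      stats::reformulate(covariates, intercept = FALSE), data = data
    )
    X0 <- cbind(X0, mm)
  }
  y <- data$y
  n <- length(y)
  rss <- vapply(candidates, function(k) {
    h <- ifelse(data$x > log(k), data$x - log(k), 0)
    sum(stats::lm.fit(cbind(X0, .hinge = h), y)$residuals^2)
  }, numeric(1))
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)

  best <- which.min(rss)  # candidates ascending -> ties go to smallest knot
  knot <- candidates[[best]]
  structure(list(
    knot = knot,
    fit = fit_piecewise(data, knot, covariates = covariates),
    profile = data.frame(knot = candidates, loglik = loglik, rss = rss)
  ), class = "knot_search")
}

#' Compare two fits by AIC
#'
#' Both fits must have been estimated on the same rows; the AIC convention
#' is the full Gaussian log-likelihood (constants included) with the
#' residual SD counted as a parameter, i.e. `stats::AIC` for an `lm`.
#'
#' @param fit_a,fit_b `scaling_fit` objects on the identical dataset.
#' @return list with `aic_a`, `aic_b`, `delta` (= aic_a - aic_b).
#' @export
compare_aic <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "scaling_fit"), inherits(fit_b, "scaling_fit"))
  if (fit_a$n != fit_b$n || !setequal(fit_a$unit_id, fit_b$unit_id)) {
    stop("fits are not on the same dataset", call. = FALSE)
  }
  list(aic_a = fit_a$aic, aic_b = fit_b$aic, delta = fit_a$aic - fit_b$aic)
}

#' Classify the scaling regime from an exponent's confidence interval
#'
#' Superlinear if the CI lower bound exceeds 1 (outcome disproportionately
#' higher in larger units), sublinear if the upper bound is below 1, linear
#' (proportional) otherwise.
#'
#' @param beta point estimate of the scaling exponent.
#' @param ci length-2 numeric interval (lower, upper).
#' @return list of class `regime_class` with `regime` (one of
#'   `"sublinear"`, `"linear"`, `"superlinear"`), `beta`, `basis` (the CI).
#' @examples
#' classify_regime(1.36, c(1.23, 1.50))$regime  # "superlinear"
#' @export
classify_regime <- function(beta, ci) {
  stopifnot(is.numeric(ci), length(ci) == 2, ci[1] <= ci[2])
  regime <- if (ci[1] > 1) "superlinear" else if (ci[2] < 1) "sublinear"
            else "linear"
  structure(list(regime = regime, beta = beta, basis = ci),
            class = "regime_class")
}

#' Fit scaling models separately within strata
#'
#' Estimates an independent model per stratum (e.g. census region, or
#' metro/micro CBSA type): the single-regime model when `knot` is NULL,
#' otherwise the two-regime model at the given fixed knot. Strata whose
#' data fail the fit preconditions are reported in the `skipped` attribute
#' with the reason — never silently dropped.
#'
#' @inheritParams fit_power_law
#' @param by name of the stratum column in `data`.
#' @param knot optional fixed knot (population value) for piecewise fits.
#' @return named list of fits, one per stratum that could be fit;
#'   attribute `skipped` is a named character vector of failure reasons.
#' @export
fit_stratified <- function(data, by, knot = NULL, covariates = NULL) {
  check_loglog(data, covariates)
  if (!by %in% names(data)) {
    stop(sprintf("stratum column '%s' not in data", by), call. = FALSE)
  }
  strata <- split(data, data[[by]], drop = TRUE)
  fits <- list()
  skipped <- character(0)
  for (s in names(strata)) {
    res <- tryCatch({
      if (is.null(knot)) fit_power_law(strata[[s]], covariates = covariates)
      else fit_piecewise(strata[[s]], knot, covariates = covariates)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[s]] <- conditionMessage(res)
      message(sprintf("stratum '%s' skipped: %s", s, conditionMessage(res)))
    } else {
      fits[[s]] <- res
    }
  }
  attr(fits, "skipped") <- skipped
  fits
}

#' Empirical percentile of a value within a sample (midpoint rule)
#'
#' percentile = 100 (#\{below\} + 0.5 #\{equal\}) / n.
#'
#' @param value the value to place (e.g. a knot population).
#' @param populations numeric sample.
#' @return percentile in \[0, 100\].
#' @export
percentile_of <- function(value, populations) {
  stopifnot(length(populations) > 0)
  100 * (sum(populations < value) + 0.5 * sum(populations == value)) /
    length(populations)
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law scaling fit (n = %d)\n  beta  = %.3f  [%.3f, %.3f]\n  alpha = %.3f  sigma = %.3f  AIC = %.1f\n",
    x$n, x$beta, x$beta_ci[1], x$beta_ci[2], x$alpha, x$sigma, x$aic
  ))
  invisible(x)
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf(
    "Two-regime scaling fit (n = %d; knot = %s; %d below / %d above)\n  beta1 = %.3f  [%.3f, %.3f]\n  beta2 = %.3f  [%.3f, %.3f]\n  alpha = %.3f  sigma = %.3f  AIC = %.1f\n",
    x$n, format(x$knot, big.mark = ","), x$n_below, x$n_above,
    x$beta1, x$beta1_ci[1], x$beta1_ci[2],
    x$beta2, x$beta2_ci[1], x$beta2_ci[2],
    x$alpha, x$sigma, x$aic
  ))
  invisible(x)
}

#' Flatten a fit to a key-value report
#'
#' @param fit a `scaling_fit`.
#' @return named list of scalars suitable for JSON serialization.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "scaling_fit"))
  base <- list(model = fit$model, n = fit$n, alpha = fit$alpha,
               sigma = fit$sigma, loglik = fit$loglik, aic = fit$aic)
  if (fit$model == "power_law") {
    cls <- classify_regime(fit$beta, fit$beta_ci)
    extra <- list(beta = fit$beta, beta_lo = fit$beta_ci[1],
                  beta_hi = fit$beta_ci[2], regime = cls$regime)
  } else {
    cls1 <- classify_regime(fit$beta1, fit$beta1_ci)
    cls2 <- classify_regime(fit$beta2, fit$beta2_ci)
    extra <- list(beta1 = fit$beta1, beta1_lo = fit$beta1_ci[1],
                  beta1_hi = fit$beta1_ci[2], regime_below = cls1$regime,
                  beta2 = fit$beta2, beta2_lo = fit$beta2_ci[1],
                  beta2_hi = fit$beta2_ci[2], regime_above = cls2$regime,
                  knot = fit$knot, n_below = fit$n_below,
                  n_above = fit$n_above)
  }
  cov <- if (is.null(fit$covariate_coefs)) list()
         else as.list(fit$covariate_coefs)
  c(base, extra, if (length(cov)) list(covariate_coefs = cov))
}

#' Write a fit report to JSON
#'
#' @param fit a `scaling_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(fit_report(fit), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
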