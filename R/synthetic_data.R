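#' Configuration for the synthetic spatial-unit generator
#'
#' Describes the generative model the scaling analysis assumes: unit
#' populations drawn from a heavy-tailed law spanning roughly 1e4–2e7
#' persons (the commuting-zone range), pill totals following a continuous
#' two-regime power law of population with multiplicative log-normal noise,
#' and census-region labels. Defaults reproduce the study-scale conditions:
#' 607 units, intercept 5, below/above-knot exponents 1.36 and 0.92, knot
#' at 82,363 persons, log-scale noise SD 0.4, and region weights
#' proportional to the study's regional unit counts (202/38/248/119).
#'
#' @param n_units number of spatial units.
#' @param pop_law population law: `"log_uniform"` (default; uniform in
#'   ln-population over `pop_range`), `"log_normal"` (parameters `meanlog`,
#'   `sdlog`, truncated to `pop_range`), or `"zipf"` (truncated Pareto with
#'   tail `exponent` on `pop_range`).
#' @param pop_range population support (persons), default `c(1e4, 2e7)`.
#' @param meanlog,sdlog log-normal parameters (log persons).
#' @param exponent Pareto tail exponent (> 1) for `"zipf"`.
#' @param alpha_true intercept on the log scale.
#' @param beta1_true below-knot scaling exponent.
#' @param beta2_true above-knot scaling exponent.
#' @param knot_true knot position (persons); must lie inside `pop_range`.
#' @param sigma_noise SD of additive Gaussian noise on ln(pills); >= 0.
#' @param region_weights named 4-vector of region probabilities summing
#'   to 1.
#' @param n_counties_per_unit optional integer range (length 1 or 2) of
#'   counties per unit for [disaggregate_to_counties()].
#' @param seed integer RNG seed; identical config + seed regenerates the
#'   dataset bit-identically.
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_units = 607,
                             pop_law = c("log_uniform", "log_normal", "zipf"),
                             pop_range = c(1e4, 2e7),
                             meanlog = log(8e4), sdlog = 1.2,
                             exponent = 1.8,
                             alpha_true = 5,
                             beta1_true = 1.36,
                             beta2_true = 0.92,
                             knot_true = 82363,
                             sigma_noise = 0.4,
                             region_weights = c(Northeast = 38, Midwest = 202,
                                                South = 248, West = 119) / 607,
                             n_counties_per_unit = NULL,
                             seed = 1L) {
  pop_law <- match.arg(pop_law)
  stopifnot(
    is.numeric(n_units), n_units >= 1,
    length(pop_range) == 2, pop_range[1] > 0, pop_range[2] > pop_range[1],
    is.numeric(sigma_noise), sigma_noise >= 0,
    is.numeric(knot_true), length(knot_true) == 1,
    is.numeric(seed), length(seed) == 1
  )
  if (knot_true <= pop_range[1] || knot_true >= pop_range[2]) {
    stop("knot_true must lie strictly inside pop_range", call. = FALSE)
  }
  if (length(region_weights) != 4 ||
      abs(sum(region_weights) - 1) > 1e-8 || any(region_weights < 0)) {
    stop("region_weights must be a non-negative 4-vector summing to 1",
         call. = FALSE)
  }
  if (is.null(names(region_weights))) {
    names(region_weights) <- region_levels()
  }
  if (!is.null(n_counties_per_unit)) {
    stopifnot(length(n_counties_per_unit) %in% 1:2,
              all(n_counties_per_unit >= 1))
    n_counties_per_unit <- as.integer(round(range(n_counties_per_unit)))
  }
  if (pop_law == "zipf" && exponent <= 1) {
    stop("zipf exponent must exceed 1", call. = FALSE)
  }
  structure(list(
    n_units = as.integer(n_units), pop_law = pop_law, pop_range = pop_range,
    meanlog = meanlog, sdlog = sdlog, exponent = exponent,
    alpha_true = alpha_true, beta1_true = beta1_true,
    beta2_true = beta2_true, knot_true = knot_true,
    sigma_noise = sigma_noise, region_weights = region_weights,
    n_counties_per_unit = n_counties_per_unit, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @keywords internal
draw_populations <- function(config) {
  n <- config$n_units
  lo <- config$pop_range[1]
  hi <- config$pop_range[2]
  switch(config$pop_law,
    log_uniform = exp(stats::runif(n, log(lo), log(hi))),
    log_normal = {
      # inverse-CDF draw truncated to the support
      plo <- stats::plnorm(lo, config$meanlog, config$sdlog)
      phi <- stats::plnorm(hi, config$meanlog, config$sdlog)
      stats::qlnorm(stats::runif(n, plo, phi), config$meanlog, config$sdlog)
    },
    zipf = {
      # truncated Pareto, P(X > x) ~ x^(1-exponent) on [lo, hi]
      a <- config$exponent - 1
      u <- stats::runif(n)
      (lo^(-a) - u * (lo^(-a) - hi^(-a)))^(-1 / a)
    }
  )
}

#' Generate a synthetic spatial-unit dataset with stored ground truth
#'
#' Draws unit populations from the configured law and pill totals from
#' ln(Y) = alpha + beta1 ln(N) + (beta2 - beta1)(ln N - ln k) 1\[N > k\]
#' + eps, eps ~ Normal(0, sigma_noise^2), rounding Y to a positive integer
#' (pill counts are counts; the rounding perturbation vanishes at
#' realistic magnitudes). Regions are drawn from the configured weights
#' and each unit is assigned a state within its region so the county
#' disaggregation can exercise the full aggregation pipeline.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_dataset`: `units` (a unit table as
#'   from [aggregate_to_units()]), `truth` (the config, plus anything
#'   later stages record, e.g. injected outlier ids), `states` (one state
#'   code per unit).
#' @export
generate_units <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n <- config$n_units
  N <- draw_populations(config)
  lnN <- log(N)
  lk <- log(config$knot_true)
  mean_lnY <- config$alpha_true + config$beta1_true * lnN +
    (config$beta2_true - config$beta1_true) * ifelse(N > config$knot_true,
                                                     lnN - lk, 0)
  lnY <- mean_lnY + stats::rnorm(n, 0, config$sigma_noise)
  Y <- pmax(round(exp(lnY)), 1)

  region <- sample(names(config$region_weights), n, replace = TRUE,
                   prob = config$region_weights)
  rmap <- census_region_map()
  state <- vapply(region, function(r) {
    pool <- setdiff(names(rmap)[rmap == r], c("AK", "HI"))
    pool[[sample.int(length(pool), 1)]]
  }, character(1))

  units <- data.frame(
    unit_id = sprintf("SU%05d", seq_len(n)),
    pills_total = as.numeric(Y),
    pop_mean = N,
    region = region,
    stratum = NA_character_,
    n_counties = 1L,
    stringsAsFactors = FALSE
  )
  structure(list(units = units, truth = config, states = unname(state)),
            class = "synthetic_dataset")
}

#' Disaggregate synthetic units into county-level input tables
#'
#' Splits each unit's population across counties by a symmetric Dirichlet
#' draw and its pills by a multinomial draw with probabilities proportional
#' to the county population shares (and uniform across window years), so
#' that [aggregate_to_units()] reproduces the unit pill totals exactly and
#' the populations within rounding. Emits the same CSV-ready schemas the
#' aggregation stage reads, closing the loop for end-to-end runs with no
#' external data.
#'
#' @param dataset a `synthetic_dataset` whose config sets
#'   `n_counties_per_unit`.
#' @param years window years to spread records over (default 2006:2014).
#' @param seed RNG seed for the split (default: the config seed + 1).
#' @return list with data.frames `pills` (county_fips, year, pills),
#'   `pops` (county_fips, year, population), `xwalk` (county_fips,
#'   unit_id, unit_kind, state).
#' @export
disaggregate_to_counties <- function(dataset, years = 2006:2014,
                                     seed = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  rng <- dataset$truth$n_counties_per_unit
  if (is.null(rng)) {
    stop("config does not set n_counties_per_unit", call. = FALSE)
  }
  if (length(rng) == 1) rng <- c(rng, rng)
  set.seed(if (is.null(seed)) dataset$truth$seed + 1L else as.integer(seed))

  units <- dataset$units
  ny <- length(years)
  pills_l <- vector("list", nrow(units))
  pops_l <- vector("list", nrow(units))
  xwalk_l <- vector("list", nrow(units))
  fips_next <- 10001L

  for (i in seq_len(nrow(units))) {
    m <- if (rng[1] == rng[2]) rng[1] else sample(rng[1]:rng[2], 1)
    shares <- stats::rgamma(m, shape = 1)
    shares <- shares / sum(shares)
    cpop <- pmax(round(shares * units$pop_mean[[i]]), 1)
    fips <- sprintf("%05d", fips_next + seq_len(m) - 1L)
    fips_next <- fips_next + m

    # split pills over county x year cells, prob ~ population share / year;
    # totals can exceed integer range, so allocate the floor of the
    # expectation first and draw only the small remainder multinomially
    # (conserves the total exactly)
    prob <- rep(cpop / sum(cpop) / ny, each = ny)
    total <- units$pills_total[[i]]
    base <- floor(total * prob)
    rem <- total - sum(base)
    cells <- base + as.vector(stats::rmultinom(1, size = rem, prob = prob))
    pills_l[[i]] <- data.frame(
      county_fips = rep(fips, each = ny),
      year = rep(years, times = m),
      pills = cells,
      stringsAsFactors = FALSE
    )
    pops_l[[i]] <- data.frame(
      county_fips = rep(fips, each = ny),
      year = rep(years, times = m),
      population = rep(cpop, each = ny),
      stringsAsFactors = FALSE
    )
    xwalk_l[[i]] <- data.frame(
      county_fips = fips,
      unit_id = units$unit_id[[i]],
      unit_kind = "CZ",
      state = dataset$states[[i]],
      stringsAsFactors = FALSE
    )
  }
  list(pills = do.call(rbind, pills_l),
       pops = do.call(rbind, pops_l),
       xwalk = do.call(rbind, xwalk_l))
}

#' Inject planted outliers into a synthetic dataset
#'
#' Adds `magnitude * sigma_noise` (signed) to ln(pills) of `k` randomly
#' chosen units and records their ids in the stored truth, supporting
#' plant-and-recover tests of outlier flagging and exclusion-sensitivity
#' refits.
#'
#' @param dataset a `synthetic_dataset`.
#' @param k number of units to perturb (< n_units).
#' @param magnitude signed displacement in units of the config's
#'   `sigma_noise` (e.g. -5 for strong negative outliers).
#' @param seed optional RNG seed; default continues the current stream.
#' @return the dataset with perturbed pills and
#'   `truth$injected_ids` / `truth$injected_magnitude` recorded.
#' @export
inject_outliers <- function(dataset, k, magnitude, seed = NULL) {
  stopifnot(inherits(dataset, "synthetic_dataset"),
            k >= 0, k < dataset$truth$n_units)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (k == 0) {
    dataset$truth$injected_ids <- character(0)
    dataset$truth$injected_magnitude <- magnitude
    return(dataset)
  }
  idx <- sample.int(nrow(dataset$units), k)
  shift <- magnitude * dataset$truth$sigma_noise
  y <- dataset$units$pills_total
  y[idx] <- pmax(round(exp(log(y[idx]) + shift)), 1)
  dataset$units$pills_total <- y
  dataset$truth$injected_ids <- dataset$units$unit_id[idx]
  dataset$truth$injected_magnitude <- magnitude
  dataset
}
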