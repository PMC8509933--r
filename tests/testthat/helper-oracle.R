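# Independent brute-force oracles and tiny fixture builders.
# The oracle path never calls the package's fitting code.

# normal-equations least squares: beta = (X'X)^{-1} X'y, plus the Gaussian
# ML log-likelihood and coefficient covariance, computed from explicit sums
ne_solve <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  n <- length(y)
  p <- ncol(X)
  rss <- sum(resid^2)
  sigma2_ml <- rss / n
  list(
    beta = unname(drop(beta)),
    resid = unname(drop(resid)),
    rss = rss,
    sigma = sqrt(rss / (n - p)),
    loglik = -n / 2 * (log(2 * pi) + log(sigma2_ml) + 1),
    vcov = solve(XtX) * rss / (n - p)
  )
}

# explicit hinge basis for the continuous two-regime model
hinge_basis <- function(x, knot) {
  lk <- log(knot)
  cbind(1, x, ifelse(x > lk, x - lk, 0))
}

# deterministic log-log toy dataset
toy_loglog <- function(x, y) {
  data.frame(unit_id = sprintf("u%02d", seq_along(x)), x = x, y = y,
             population = exp(x), stringsAsFactors = FALSE)
}

# noiseless two-regime data on given ln-populations
piecewise_mean <- function(x, alpha, beta1, beta2, knot) {
  lk <- log(knot)
  alpha + beta1 * x + (beta2 - beta1) * ifelse(x > lk, x - lk, 0)
}

# hand-rolled 6-county / 3-unit / 2-year aggregation fixture with values
# chosen so totals are easy to sum independently
toy_county_fixture <- function() {
  counties <- sprintf("%05d", c(10101, 10102, 20201, 20202, 30301, 30302))
  units <- rep(c("CZ001", "CZ002", "CZ003"), each = 2)
  pills <- expand.grid(county_fips = counties, year = 2006:2007,
                       stringsAsFactors = FALSE)
  pills$pills <- c(10, 20, 30, 40, 50, 60,   # 2006
                   11, 21, 31, 41, 51, 61)   # 2007
  pops <- expand.grid(county_fips = counties, year = 2006:2007,
                      stringsAsFactors = FALSE)
  pops$population <- c(100, 200, 300, 400, 500, 600,
                       110, 210, 310, 410, 510, 610)
  xwalk <- data.frame(county_fips = counties, unit_id = units,
                      unit_kind = "CZ",
                      state = c("OH", "OH", "TX", "TX", "CA", "CA"),
                      stringsAsFactors = FALSE)
  list(pills = pills, pops = pops, xwalk = xwalk)
}
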