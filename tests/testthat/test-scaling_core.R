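test_that("an exact line is recovered with zero residual SD", {
  d <- toy_loglog(x = 1:10, y = 2 + 1 * (1:10))
  f <- suppressWarnings(fit_power_law(d))  # perfect-fit summary warning
  expect_equal(f$alpha, 2, tolerance = 1e-10)
  expect_equal(f$beta, 1, tolerance = 1e-10)
  expect_lt(f$sigma, 1e-10)
})

test_that("single-regime OLS matches the closed-form normal-equations oracle", {
  x <- c(9.2, 10.1, 11.7, 13.4, 15.8)
  y <- c(14.1, 15.9, 17.2, 19.9, 21.4)
  d <- toy_loglog(x, y)
  f <- fit_power_law(d)
  o <- ne_solve(cbind(1, x), y)
  expect_equal(f$alpha, o$beta[1], tolerance = 1e-8)
  expect_equal(f$beta, o$beta[2], tolerance = 1e-8)
  expect_equal(f$sigma, o$sigma, tolerance = 1e-8)
  expect_equal(f$loglik, o$loglik, tolerance = 1e-8)
  # CI from the t distribution with n - p df
  se <- sqrt(o$vcov[2, 2])
  tq <- qt(0.975, length(x) - 2)
  expect_equal(f$beta_ci, c(o$beta[2] - tq * se, o$beta[2] + tq * se),
               tolerance = 1e-8)
  # AIC arithmetic: -2 loglik + 2 * (alpha, beta, sigma)
  expect_equal(f$aic, -2 * o$loglik + 2 * 3, tolerance = 1e-8)
})

test_that("noiseless two-regime data is recovered exactly at the true knot", {
  x <- seq(log(1e4), log(2e7), length.out = 40)
  y <- piecewise_mean(x, alpha = 5, beta1 = 1.36, beta2 = 0.92, knot = 82363)
  f <- suppressWarnings(fit_piecewise(toy_loglog(x, y), 82363))
  expect_equal(f$alpha, 5, tolerance = 1e-8)
  expect_equal(f$beta1, 1.36, tolerance = 1e-8)
  expect_equal(f$beta2, 0.92, tolerance = 1e-8)
  expect_lt(f$sigma, 1e-8)
  expect_equal(f$n_below + f$n_above, f$n)
})

test_that("piecewise coefficients match the explicit hinge-basis oracle", {
  x <- c(9.5, 10.0, 10.8, 11.0, 11.6, 12.3, 13.8, 15.2)
  y <- c(17.9, 18.6, 20.1, 20.0, 21.1, 21.5, 23.0, 24.1)
  knot <- 80000
  d <- toy_loglog(x, y)
  f <- fit_piecewise(d, knot)
  X <- hinge_basis(x, knot)
  o <- ne_solve(X, y)
  expect_equal(f$alpha, o$beta[1], tolerance = 1e-8)
  expect_equal(f$beta1, o$beta[2], tolerance = 1e-8)
  expect_equal(f$beta2, o$beta[2] + o$beta[3], tolerance = 1e-8)
  expect_equal(f$sigma, o$sigma, tolerance = 1e-8)
  expect_equal(f$loglik, o$loglik, tolerance = 1e-8)
  # beta2 CI from the variance of the linear combination beta1 + gamma
  se2 <- sqrt(o$vcov[2, 2] + o$vcov[3, 3] + 2 * o$vcov[2, 3])
  tq <- qt(0.975, length(x) - 3)
  b2 <- o$beta[2] + o$beta[3]
  expect_equal(f$beta2_ci, c(b2 - tq * se2, b2 + tq * se2), tolerance = 1e-8)
})

test_that("fit preconditions are enforced", {
  d <- toy_loglog(x = 1:4, y = 1:4)
  expect_error(fit_power_law(d[1:2, ]), "at least 3")
  expect_error(fit_piecewise(toy_loglog(1:10, 1:10), knot = exp(1.5)),
               "fewer than 2 points")
  # rank-deficient design: covariate collinear with x
  d$dup <- d$x
  expect_error(fit_power_law(d, covariates = "dup"), "rank-deficient")
})

test_that("knot search returns the argmin of RSS over the candidate grid", {
  # noiseless: the selected candidate is the grid value nearest the truth
  set.seed(21)
  x <- sort(runif(40, log(1e4), log(2e7)))
  truth <- 82363
  y <- piecewise_mean(x, 5, 1.36, 0.92, truth)
  ks <- search_knot(toy_loglog(x, y))
  cand <- ks$profile$knot
  expect_equal(ks$knot, cand[which.min(abs(log(cand) - log(truth)))])

  # noisy 20-point fixture: equals exhaustive enumeration over all interior
  # observed populations (oracle = literal argmin of hinge-basis RSS)
  set.seed(22)
  x <- sort(runif(20, log(1e4), log(2e7)))
  y <- piecewise_mean(x, 5, 1.36, 0.92, truth) + rnorm(20, 0, 0.3)
  pops <- exp(x)
  cand <- pops[pops > min(pops) & pops < max(pops)]
  cand <- Filter(function(k) sum(x < log(k)) >= 2 && sum(x > log(k)) >= 2,
                 sort(cand))
  rss <- vapply(cand, function(k) ne_solve(hinge_basis(x, k), y)$rss,
                numeric(1))
  oracle_knot <- cand[which.min(rss)]
  ks2 <- search_knot(toy_loglog(x, y), candidates = pops)
  expect_equal(ks2$knot, oracle_knot)
  expect_equal(ks2$fit$beta1,
               ne_solve(hinge_basis(x, oracle_knot), y)$beta[2],
               tolerance = 1e-8)
  # profile is returned for diagnostics, likelihood consistent with RSS
  expect_true(all(diff(ks2$profile$loglik[order(ks2$profile$rss)]) <= 1e-10))
})

test_that("AIC comparison checks datasets and does plain arithmetic", {
  set.seed(23)
  x <- seq(log(1e4), log(2e7), length.out = 12)
  y <- piecewise_mean(x, 5, 1.36, 0.92, 82363) + rnorm(12, 0, 0.3)
  d <- toy_loglog(x, y)
  f1 <- fit_power_law(d)
  f2 <- fit_piecewise(d, 82363)
  expect_equal(compare_aic(f1, f1)$delta, 0)
  cmp <- compare_aic(f2, f1)
  # arithmetic oracle: AIC = -2 loglik + 2k, k counting sigma
  expect_equal(cmp$aic_a, -2 * f2$loglik + 2 * 4, tolerance = 1e-10)
  expect_equal(cmp$aic_b, -2 * f1$loglik + 2 * 3, tolerance = 1e-10)
  expect_equal(cmp$delta, cmp$aic_a - cmp$aic_b)
  expect_error(compare_aic(f1, fit_power_law(d[1:10, ])), "same dataset")
})

test_that("scale invariance: rescaling Y shifts alpha by ln(c) and nothing else", {
  set.seed(24)
  x <- sort(runif(60, log(1e4), log(2e7)))
  y <- piecewise_mean(x, 5, 1.36, 0.92, 82363) + rnorm(60, 0, 0.4)
  d <- toy_loglog(x, y)
  cc <- 1000   # multiply all pill counts by c <=> add ln(c) to y
  d2 <- d
  d2$y <- d$y + log(cc)
  for (fitter in list(
    function(dd) fit_power_law(dd),
    function(dd) fit_piecewise(dd, 82363)
  )) {
    f <- fitter(d)
    g <- fitter(d2)
    expect_equal(g$alpha, f$alpha + log(cc), tolerance = 1e-8)
    expect_equal(g$sigma, f$sigma, tolerance = 1e-8)
    if (f$model == "power_law") {
      expect_equal(g$beta, f$beta, tolerance = 1e-10)
      expect_equal(g$beta_ci, f$beta_ci, tolerance = 1e-10)
    } else {
      expect_equal(g$beta1, f$beta1, tolerance = 1e-10)
      expect_equal(g$beta2, f$beta2, tolerance = 1e-10)
      expect_equal(g$beta1_ci, f$beta1_ci, tolerance = 1e-10)
      expect_equal(g$beta2_ci, f$beta2_ci, tolerance = 1e-10)
    }
  }
  dAIC1 <- compare_aic(fit_piecewise(d, 82363), fit_power_law(d))$delta
  dAIC2 <- compare_aic(fit_piecewise(d2, 82363), fit_power_law(d2))$delta
  expect_equal(dAIC1, dAIC2, tolerance = 1e-8)
})

test_that("the spline model nests the line: RSS never increases, loglik never drops", {
  set.seed(25)
  for (rep in 1:20) {
    x <- sort(runif(30, log(1e4), log(2e7)))
    y <- 5 + 1.1 * x + rnorm(30, 0, 0.5)
    d <- toy_loglog(x, y)
    f1 <- fit_power_law(d)
    f2 <- fit_piecewise(d, exp(stats::median(x)))
    expect_lte(sum(f2$residuals^2), sum(f1$residuals^2) + 1e-10)
    expect_gte(f2$loglik, f1$loglik - 1e-10)
  }
})

test_that("the fitted mean is continuous at the knot", {
  set.seed(26)
  x <- sort(runif(50, log(1e4), log(2e7)))
  y <- piecewise_mean(x, 5, 1.36, 0.92, 82363) + rnorm(50, 0, 0.4)
  f <- fit_piecewise(toy_loglog(x, y), 82363)
  lk <- log(f$knot)
  mean_at <- function(xx) {
    f$alpha + f$beta1 * xx +
      (f$beta2 - f$beta1) * ifelse(xx > lk, xx - lk, 0)
  }
  for (delta in 10^(-(4:10))) {
    gap <- abs(mean_at(lk + delta) - mean_at(lk - delta))
    expect_lt(gap, 3 * delta)   # -> 0 linearly in delta
  }
  expect_equal(mean_at(lk - 1e-12), mean_at(lk + 1e-12), tolerance = 1e-10)
})

test_that("with no slope change the hinge CI covers zero at the nominal rate", {
  covered <- vapply(1:500, function(i) {
    set.seed(30000 + i)
    x <- runif(200, log(1e4), log(2e7))
    y <- 5 + 1.1 * x + rnorm(200, 0, 0.4)   # beta1 = beta2
    f <- fit_piecewise(toy_loglog(x, y), 82363)
    f$hinge_ci[1] <= 0 && 0 <= f$hinge_ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("estimation error shrinks as noise drops and sample size grows", {
  rmse_at <- function(n, sigma, seeds) {
    err <- vapply(seeds, function(s) {
      d <- generate_units(synthetic_config(n_units = n, sigma_noise = sigma,
                                           seed = s))
      f <- fit_piecewise(log_log_data(d$units), 82363)
      (f$beta1 - 1.36)^2 + (f$beta2 - 0.92)^2
    }, numeric(1))
    sqrt(mean(err))
  }
  seeds <- 40000 + 1:150
  ladder_n <- vapply(c(50, 200, 1000), rmse_at, numeric(1),
                     sigma = 0.4, seeds = seeds)
  expect_true(all(diff(ladder_n) < 0))
  ladder_s <- vapply(c(0.4, 0.2, 0.05), function(s) {
    rmse_at(200, s, seeds)
  }, numeric(1))
  expect_true(all(diff(ladder_s) < 0))
})

test_that("regime classification follows the CI-versus-one rule", {
  expect_equal(classify_regime(1.36, c(1.23, 1.50))$regime, "superlinear")
  expect_equal(classify_regime(0.92, c(0.88, 0.95))$regime, "sublinear")
  expect_equal(classify_regime(1.00, c(0.93, 1.06))$regime, "linear")
  # CI touching 1 is not beyond it
  expect_equal(classify_regime(1.1, c(1.0, 1.2))$regime, "linear")
  expect_error(classify_regime(1, c(2, 1)))
})

test_that("covariate adjustment enters additively and reports coefficients", {
  set.seed(27)
  x <- runif(300, log(1e4), log(2e7))
  reg <- sample(c("South", "West"), 300, replace = TRUE)
  y <- 5 + 1.2 * x + 0.3 * (reg == "West") + rnorm(300, 0, 0.3)
  d <- toy_loglog(x, y)
  d$region <- reg
  f <- fit_power_law(d, covariates = "region")
  expect_named(f$covariate_coefs, "regionWest")
  expect_equal(unname(f$covariate_coefs), 0.3, tolerance = 0.15)
  # oracle check on the dummy design
  o <- ne_solve(cbind(1, x, as.numeric(reg == "West")), y)
  expect_equal(f$beta, o$beta[2], tolerance = 1e-8)
  expect_equal(unname(f$covariate_coefs), o$beta[3], tolerance = 1e-8)
})

test_that("stratified fitting reproduces per-stratum fits and reports failures", {
  set.seed(28)
  x <- runif(120, log(1e4), log(2e7))
  y <- 5 + 1.2 * x + rnorm(120, 0, 0.3)
  d <- toy_loglog(x, y)
  d$region <- "All"
  fits <- fit_stratified(d, by = "region")
  expect_equal(fits$All$beta, fit_power_law(d)$beta)

  # four regions with known slopes, recovered within Monte-Carlo tolerance
  slopes <- c(Northeast = 1.05, Midwest = 1.42, South = 1.17, West = 1.39)
  reg <- rep(names(slopes), each = 150)
  x <- runif(600, log(1e4), log(2e7))
  y <- 5 + slopes[reg] * x + rnorm(600, 0, 0.4)
  d4 <- toy_loglog(x, y)
  d4$region <- reg
  fits4 <- fit_stratified(d4, by = "region")
  for (r in names(slopes)) {
    expect_equal(fits4[[r]]$beta, unname(slopes[r]), tolerance = 0.05)
  }

  # a stratum too small to fit is reported, not silently dropped
  d4$region[1] <- "Tiny"
  d4 <- d4[c(1, which(d4$region != "Tiny")), ]
  expect_message(fits5 <- fit_stratified(d4, by = "region"), "Tiny")
  expect_named(attr(fits5, "skipped"), "Tiny")
  expect_length(fits5, 4)
})

test_that("percentile_of implements the midpoint counting rule", {
  v <- c(5, 8, 8, 12, 20)
  expect_equal(percentile_of(5, v), 100 * 0.5 / 5)     # minimum
  expect_equal(percentile_of(8, v), 100 * (1 + 0.5 * 2) / 5)
  expect_equal(percentile_of(100, v), 100)
  set.seed(29)
  w <- sample(1:50, 20, replace = TRUE)
  val <- w[7]
  oracle <- 100 * (sum(w < val) + 0.5 * sum(w == val)) / 20
  expect_equal(percentile_of(val, w), oracle)
})

test_that("fit reports serialize to flat JSON and back", {
  set.seed(31)
  x <- runif(40, log(1e4), log(2e7))
  y <- piecewise_mean(x, 5, 1.36, 0.92, 82363) + rnorm(40, 0, 0.4)
  f <- fit_piecewise(toy_loglog(x, y), 82363)
  rep <- fit_report(f)
  expect_equal(rep$beta1, f$beta1)
  expect_equal(rep$knot, 82363)
  expect_true(rep$regime_below %in% c("sublinear", "linear", "superlinear"))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$beta1, f$beta1, tolerance = 1e-12)
  expect_equal(back$aic, f$aic, tolerance = 1e-12)
})
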