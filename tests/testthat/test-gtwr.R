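# GTWR core: space-time distances, kernels, pointwise WLS, full fits,
# CV calibration, OLS baseline and the non-stationarity test.

make_panel <- function(n_cities = 25, years = 2012:2015, seed = 2,
                       noise_sd = 0.3, surfaces = NULL, vars = c("pgdp", "hp")) {
  cov <- default_covariates()
  cov <- cov[cov$variable %in% vars, ]
  if (is.null(surfaces))
    surfaces <- c(list(intercept = surface_spec("constant", base_value = 10)),
                  setNames(lapply(vars, function(v)
                    surface_spec("constant", base_value = 0.5)), vars))
  cfg <- synthetic_config(n_cities = n_cities, years = years,
                          covariates = cov,
                          coefficient_surfaces = surfaces,
                          noise_sd = noise_sd, missing_rate = 0, seed = seed)
  simulate_panel(cfg)
}

test_that("space-time squared distance follows its closed form", {
  expect_equal(st_distance_sq(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(st_distance_sq(c(0, 0, 2012), c(3, 4, 2020),
                              lambda = 1, mu = 0), 25)
  expect_equal(st_distance_sq(c(0, 0, 0), c(1, 3, 3),
                              lambda = 0.5, mu = 2), 0.5 * 10 + 2 * 9)
  expect_error(st_distance_sq(c(0, 0, 0), c(1, 1, 1), lambda = 0),
               class = "invalid_config")
})

test_that("kernel weights hit their landmark values", {
  g <- kernel_spec("gaussian", bandwidth = 2)
  b <- kernel_spec("bisquare", bandwidth = 2)
  expect_equal(kernel_weight(0, g), 1)
  expect_equal(kernel_weight(0, b), 1)
  expect_equal(kernel_weight(4, g), exp(-1))     # d = h
  expect_equal(kernel_weight(4, b), 0)           # d >= h
  expect_equal(kernel_weight(1, b), (1 - 0.25)^2)
  expect_error(kernel_spec("gaussian", bandwidth = 0),
               class = "invalid_config")
})

test_that("pointwise WLS equals the normal-equations oracle", {
  # unit weights reduce to OLS
  set.seed(4)
  X <- cbind(1, rnorm(10), rnorm(10))
  y <- rnorm(10)
  expect_equal(unname(fit_pointwise(X, y, rep(1, 10))),
               unname(coef(lm(y ~ X[, 2] + X[, 3]))), tolerance = 1e-10)

  # noiseless line is interpolated exactly under any positive weights
  x <- 1:6
  yl <- 2 + 3 * x
  expect_equal(unname(fit_pointwise(cbind(1, x), yl, runif(6, 0.1, 2))),
               c(2, 3), tolerance = 1e-10)

  # 4-point weighted system vs explicit (X'WX)^{-1}X'Wy
  X4 <- cbind(1, c(0, 1, 2, 3))
  y4 <- c(1, 2.2, 2.9, 4.4)
  w4 <- c(1, 1, 0.5, 0.25)
  expect_lt(max(abs(fit_pointwise(X4, y4, w4) - drop(bf_wls(X4, y4, w4)))),
            1e-10)

  # oracle equivalence over random small systems (n <= 8)
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    p <- sample(1:(n - 1), 1)
    Xr <- cbind(1, matrix(rnorm(n * (p - 1)), n))[, 1:p, drop = FALSE]
    yr <- rnorm(n)
    wr <- runif(n, 0.05, 2)
    expect_lt(max(abs(fit_pointwise(Xr, yr, wr) - drop(bf_wls(Xr, yr, wr)))),
              1e-10)
  }
})

test_that("rank-deficient or underdetermined local fits are handled", {
  set.seed(1)
  y <- rnorm(4)
  # exactly collinear design: the ridge fallback still yields a finite fit
  X <- cbind(1, c(1, 1, 1, 1))
  expect_true(all(is.finite(fit_pointwise(X, y, rep(1, 4)))))
  # an unsalvageable system raises the named error
  expect_error(fit_pointwise(cbind(1, rep(NaN, 4)), y, rep(1, 4)),
               class = "singular_fit")
  expect_error(fit_pointwise(cbind(1, 1:4), y, c(1, 0, 0, 0)),
               class = "underdetermined_fit")
})

test_that("GTWR collapses to OLS as the bandwidth grows", {
  p <- make_panel(seed = 7)
  fit <- gtwr(birth_rate ~ pgdp + hp, p, bandwidth = 1e9, tau = 0)
  ols <- fit_ols(birth_rate ~ pgdp + hp, p)
  expect_lt(max(abs(sweep(coef(fit), 2, coef(ols)))), 1e-6)
  expect_lt(abs(fit$adj_r2 - ols$adj_r2), 1e-6)
})

test_that("mu = 0 makes the fit blind to time (pure GWR)", {
  p <- make_panel(seed = 9)
  fit1 <- gtwr(birth_rate ~ pgdp + hp, p, bandwidth = 250, tau = 0)
  p2 <- p
  p2$year <- sample(p2$year)   # scramble time; mu = 0 must not care
  fit2 <- gtwr(birth_rate ~ pgdp + hp, p2, bandwidth = 250, tau = 0)
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-12)
})

test_that("fit identities and hat-trace bounds hold", {
  p <- make_panel(seed = 13)
  fit <- gtwr(birth_rate ~ pgdp + hp, p, bandwidth = 200, tau = 0)
  expect_equal(fit$fitted + fit$residuals, fit$y, tolerance = 1e-12)
  expect_lte(fit$adj_r2, 1)
  expect_gt(fit$hat_trace, fit$p)
  expect_lt(fit$hat_trace, fit$n)

  # tr(S) is non-increasing in h
  traces <- vapply(c(60, 120, 240, 480, 1000, 5000), function(h)
    gtwr(birth_rate ~ pgdp + hp, p, bandwidth = h, tau = 0)$hat_trace, 0.0)
  expect_true(all(diff(traces) <= 1e-8))
})

test_that("CV score has its limiting and degenerate behaviours", {
  p <- make_panel(n_cities = 15, years = 2012:2013, seed = 21)
  # bisquare with near-zero bandwidth isolates every point
  expect_equal(cv_score(birth_rate ~ pgdp + hp, p, bandwidth = 1e-6,
                        kernel = "bisquare"), Inf)
  # huge bandwidth approaches OLS leave-one-out PRESS
  cv <- cv_score(birth_rate ~ pgdp + hp, p, bandwidth = 1e9)
  m <- lm(birth_rate ~ pgdp + hp, p)
  press <- sum((residuals(m) / (1 - hatvalues(m)))^2)
  expect_equal(cv, press, tolerance = 1e-4)
  expect_gte(cv, 0)
})

test_that("bandwidth calibration is deterministic and finds temporal structure", {
  surfaces <- list(intercept = surface_spec("constant", base_value = 10),
                   pgdp = surface_spec("linear_time", base_value = 1,
                                       time_slope = -0.8),
                   hp = surface_spec("constant", base_value = 0.3))
  p <- make_panel(n_cities = 40, years = 2012:2016, seed = 17,
                  noise_sd = 0.2, surfaces = surfaces)
  s1 <- gtwr_bandwidth(birth_rate ~ pgdp + hp, p)
  s2 <- gtwr_bandwidth(birth_rate ~ pgdp + hp, p)
  expect_identical(s1$bandwidth, s2$bandwidth)
  expect_identical(s1$tau, s2$tau)
  expect_gt(s1$tau, 0)          # strong coefficient drift in time

  # tau_grid = {0} reduces to purely spatial bandwidth selection
  s0 <- gtwr_bandwidth(birth_rate ~ pgdp + hp, p, tau_grid = 0)
  expect_equal(s0$tau, 0)
  expect_true(is.finite(s0$bandwidth))
})

test_that("the OLS baseline matches the oracle and its SEs scale as 1/sqrt(n)", {
  set.seed(6)
  d <- data.frame(x1 = rnorm(6), x2 = rnorm(6))
  d$y <- 1 + 2 * d$x1 - d$x2 + rnorm(6, 0, 0.1)
  ols <- fit_ols(y ~ x1 + x2, d)
  expect_lt(max(abs(ols$coefficients -
                    drop(bf_wls(cbind(1, d$x1, d$x2), d$y, rep(1, 6))))),
            1e-10)

  # exact replication: X'X doubles and sigma^2 rescales by the df ratio,
  # so se shrinks by sqrt((n - p) / (2n - p)) -- about 1/sqrt(2) at large n
  d2 <- rbind(d, d)
  ols2 <- fit_ols(y ~ x1 + x2, d2)
  expect_equal(unname(ols2$se / ols$se), rep(sqrt(3 / 9), 3),
               tolerance = 1e-10)
})

test_that("the IQR convention of the non-stationarity test is type-7", {
  fake_fit <- structure(list(coefficients = cbind(`(Intercept)` = rep(1, 11),
                                                  x = 1:11),
                             variable_names = c("(Intercept)", "x")),
                        class = "gtwr")
  fake_ols <- structure(list(se = c(`(Intercept)` = 1, x = 2.49),
                             variable_names = c("(Intercept)", "x")),
                        class = "ols_fit")
  rep1 <- nonstationarity_test(fake_fit, fake_ols)
  expect_equal(rep1$iqr_gtwr, 5)          # IQR of 1..11, linear interpolation
  expect_true(rep1$nonstationary)         # 5 > 2 * 2.49
  fake_ols$se["x"] <- 2.51
  expect_false(nonstationarity_test(fake_fit, fake_ols)$nonstationary)
})

test_that("stationary coefficients are not flagged; strongly varying ones are", {
  p <- make_panel(n_cities = 30, years = 2012:2014, seed = 23,
                  noise_sd = 0.01)
  fit <- gtwr(birth_rate ~ pgdp + hp, p, bandwidth = 1e6, tau = 0)
  ols <- fit_ols(birth_rate ~ pgdp + hp, p)
  expect_false(any(nonstationarity_test(fit, ols)$nonstationary))

  surfaces <- list(intercept = surface_spec("constant", base_value = 10),
                   pgdp = surface_spec("gaussian_bump", base_value = 0,
                                       amplitude = 3, center = c(500, 500),
                                       length_scale = 250),
                   hp = surface_spec("constant", base_value = 0.3))
  pv <- make_panel(n_cities = 60, years = 2012:2014, seed = 29,
                   noise_sd = 0.1, surfaces = surfaces)
  fitv <- gtwr(birth_rate ~ pgdp + hp, pv, bandwidth = 200, tau = 0)
  olsv <- fit_ols(birth_rate ~ pgdp + hp, pv)
  rep_v <- nonstationarity_test(fitv, olsv)
  expect_true(rep_v$nonstationary[rep_v$variable == "pgdp"])
})

test_that("prediction at the training points reproduces the fitted values", {
  p <- make_panel(n_cities = 20, years = 2012:2013, seed = 31)
  fit <- gtwr(birth_rate ~ pgdp + hp, p, bandwidth = 300, tau = 0)
  expect_equal(predict(fit, p), fit$fitted, tolerance = 1e-10)
  b <- predict(fit, p[1:4, ], coefficients = TRUE)
  expect_equal(dim(b), c(4L, 3L))

  sims <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(sims, simulate(fit, nsim = 2, seed = 5))
  expect_equal(dim(sims), c(fit$n, 2L))
})
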