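# Synthetic city-panel generator: layouts, coefficient surfaces, panel
# simulation and clustered fields.

test_that("city layouts stay in the window, are deterministic, and cluster", {
  one <- generate_city_layout(1, "uniform", seed = 7)
  expect_equal(nrow(one), 1L)
  expect_true(all(one$u >= 0 & one$u <= 1000 & one$v >= 0 & one$v <= 1000))

  a <- generate_city_layout(50, "clustered", n_clusters = 4, seed = 42)
  b <- generate_city_layout(50, "clustered", n_clusters = 4, seed = 42)
  expect_identical(a, b)
  expect_equal(anyDuplicated(a$city_id), 0L)
  expect_true(all(a$u >= 0 & a$u <= 1000 & a$v >= 0 & a$v <= 1000))

  lay <- generate_city_layout(300, "clustered", n_clusters = 5, seed = 1)
  cl <- attr(lay, "cluster")
  coords <- cbind(lay$u, lay$v)
  overall <- mean(bf_pairwise_dists(coords[sample.int(300, 60), ]))
  within <- mean(unlist(lapply(split(seq_len(300), cl), function(idx)
    bf_pairwise_dists(coords[idx, , drop = FALSE]))))
  expect_lt(within, overall)

  expect_error(generate_city_layout(3, "clustered", n_clusters = 5),
               class = "invalid_config")
})

test_that("surface evaluation matches its closed forms", {
  expect_equal(evaluate_surface(surface_spec("constant", base_value = 2.5),
                                u = c(0, 900), v = c(5, 5), t = 2012),
               c(2.5, 2.5))
  bump <- surface_spec("gaussian_bump", base_value = 0, amplitude = 1,
                       center = c(0, 0), length_scale = 1)
  expect_equal(evaluate_surface(bump, 0, 0, 2000), 1.0)
  expect_equal(evaluate_surface(bump, 1, 0, 2000), exp(-0.5))
  lt <- surface_spec("linear_time", base_value = -0.5, time_slope = -0.1)
  expect_equal(evaluate_surface(lt, 0, 0, t = 2017, t0 = 2012), -1.0)
  sep <- surface_spec("separable_product", base_value = 1, amplitude = 2,
                      center = c(0, 0), length_scale = 1, time_slope = 0.5)
  expect_equal(evaluate_surface(sep, 0, 0, t = 2014, t0 = 2012),
               (1 + 2) * (1 + 0.5 * 2))
  expect_error(surface_spec("gaussian_bump", length_scale = 0),
               class = "invalid_config")
})

test_that("simulated panels have the configured shape and are reproducible", {
  cfg <- synthetic_config(n_cities = 286, years = 2012:2021,
                          missing_rate = 0, seed = 11)
  p <- simulate_panel(cfg)
  expect_equal(nrow(p), 2860L)
  expect_identical(p$birth_rate, simulate_panel(cfg)$birth_rate)
  tr <- attr(p, "truth")
  expect_equal(nrow(tr), nrow(p))

  # covariate scale fidelity: sample means within 3 standard errors
  cov <- default_covariates()
  for (k in seq_len(nrow(cov))) {
    se <- cov$sd[k] / sqrt(nrow(p))
    expect_lt(abs(mean(p[[cov$variable[k]]]) - cov$mean[k]), 3 * se)
  }

  # missingness thins the panel at the configured rate
  cfg2 <- synthetic_config(n_cities = 286, years = 2012:2021,
                           missing_rate = 0.074, seed = 11)
  p2 <- simulate_panel(cfg2)
  expect_lt(abs(nrow(p2) - 2860 * (1 - 0.074)), 3 * sqrt(2860 * 0.074))
})

test_that("noiseless constant-surface panels are exactly linear in X", {
  vars <- c("pgdp", "hp")
  cov <- default_covariates()
  cov <- cov[cov$variable %in% vars, ]
  surfaces <- list(intercept = surface_spec("constant", base_value = 12),
                   pgdp = surface_spec("constant", base_value = -0.8),
                   hp = surface_spec("constant", base_value = 0.4))
  cfg <- synthetic_config(n_cities = 40, years = 2012:2014,
                          covariates = cov, coefficient_surfaces = surfaces,
                          noise_sd = 0, missing_rate = 0, seed = 5)
  p <- simulate_panel(cfg)
  X <- cbind(1, p$pgdp, p$hp)
  beta <- bf_wls(X, p$birth_rate, rep(1, nrow(p)))
  expect_lt(max(abs(beta - c(12, -0.8, 0.4))), 1e-8)
})

test_that("a missing coefficient surface is an invalid config", {
  cov <- default_covariates()[1:2, ]
  expect_error(
    synthetic_config(n_cities = 20, years = 2012:2013, covariates = cov,
                     coefficient_surfaces = list(
                       intercept = surface_spec("constant", base_value = 1),
                       pgdp = surface_spec("constant", base_value = 0))),
    class = "invalid_config")
})

test_that("clustered fields peak at hot centres and are unstructured at amplitude 0", {
  lay <- generate_city_layout(80, "uniform", seed = 4)
  coords <- cbind(lay$u, lay$v)
  f <- simulate_clustered_field(coords, hot_centers = c(250, 250),
                                amplitude = 5, noise_sd = 0, seed = 2)
  d2 <- (coords[, 1] - 250)^2 + (coords[, 2] - 250)^2
  expect_equal(which.max(f), which.min(d2))
  expect_identical(f, simulate_clustered_field(coords,
                                               hot_centers = c(250, 250),
                                               amplitude = 5, noise_sd = 0,
                                               seed = 2))

  flat <- simulate_clustered_field(coords, hot_centers = c(250, 250),
                                   amplitude = 0, noise_sd = 1, seed = 3)
  w <- build_weights(coords)
  m <- morans_i(flat, w, n_permutations = 499, seed = 9)
  expect_gt(m$p_permutation, 0.05)
})
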