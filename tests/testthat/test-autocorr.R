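# Global/local Moran's I and Getis-Ord Gi*.

test_that("a rook checkerboard has Moran's I of exactly -1", {
  xy <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  w <- build_weights(xy, scheme = "distance_band", band = 1,
                     row_standardize = TRUE)
  m <- morans_i(c(1, -1, -1, 1), w, n_permutations = 0)
  expect_equal(m$statistic, -1, tolerance = 1e-12)
  expect_equal(m$expected_value, -1 / 3)
})

test_that("degenerate inputs raise named errors", {
  xy <- cbind(runif(6), runif(6))
  w <- build_weights(xy)
  expect_error(morans_i(rep(3, 6), w), class = "degenerate_input")
  expect_error(local_moran(rep(0, 6), w, n_permutations = 9),
               class = "degenerate_input")
  ws <- build_weights(xy, scheme = "distance_band", band = Inf,
                      include_self = TRUE, row_standardize = FALSE)
  expect_error(getis_ord_gi_star(rep(1, 6), ws), class = "degenerate_input")
  expect_error(getis_ord_gi_star(runif(6), w), class = "invalid_config")
})

test_that("statistics match brute-force formula evaluation on a 25-point grid", {
  coords <- grid_coords(5)
  set.seed(77)
  x <- rnorm(25, 10, 3)

  w <- build_weights(coords, scheme = "inverse_distance",
                     row_standardize = TRUE)
  expect_lt(abs(morans_i(x, w, n_permutations = 0)$statistic -
                bf_moran(x, w$W)), 1e-9)

  li <- local_moran(x, w, n_permutations = 9, seed = 1)
  expect_lt(max(abs(li$local_i - bf_local_moran(x, w$W))), 1e-9)

  wg <- build_weights(coords, scheme = "distance_band", band = 15,
                      include_self = TRUE, row_standardize = FALSE)
  gi <- getis_ord_gi_star(x, wg)
  expect_lt(max(abs(gi$gi_star - bf_gi_star(x, wg$W))), 1e-9)

  # sum of local Moran equals S0 times global I (shared-convention check)
  S0 <- sum(w$W)
  expect_equal(sum(li$local_i) / S0,
               morans_i(x, w, n_permutations = 0)$statistic,
               tolerance = 1e-9)
})

test_that("the permutation null is centred at -1/(n-1) and seeded runs repeat", {
  set.seed(12)
  coords <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  w <- build_weights(coords)
  x <- rnorm(20)
  m1 <- morans_i(x, w, n_permutations = 999, seed = 5)
  m2 <- morans_i(x, w, n_permutations = 999, seed = 5)
  expect_identical(m1$p_permutation, m2$p_permutation)

  # recover the permutation distribution mean by direct simulation
  perm_mean <- mean(replicate(2000, {
    xp <- sample(x)
    (20 / sum(w$W)) * sum((xp - mean(xp)) *
                            as.numeric(w$W %*% (xp - mean(xp)))) /
      sum((xp - mean(xp))^2)
  }))
  expect_lt(abs(perm_mean - (-1 / 19)), 0.02)
})

test_that("Moran's I is invariant to positive affine transforms", {
  set.seed(3)
  coords <- cbind(runif(15, 0, 100), runif(15, 0, 100))
  w <- build_weights(coords)
  x <- rnorm(15)
  i0 <- morans_i(x, w, n_permutations = 0)$statistic
  i1 <- morans_i(3.7 * x + 42, w, n_permutations = 0)$statistic
  expect_equal(i0, i1, tolerance = 1e-12)
})

test_that("Gi* is antisymmetric under negation and spikes at the spiked city", {
  set.seed(21)
  coords <- cbind(runif(16, 0, 100), runif(16, 0, 100))
  w <- build_weights(coords, scheme = "distance_band", band = 40,
                     include_self = TRUE, row_standardize = FALSE)
  x <- rnorm(16)
  expect_equal(getis_ord_gi_star(x, w)$gi_star,
               -getis_ord_gi_star(-x, w)$gi_star, tolerance = 1e-12)

  # with equal neighbourhood sizes (knn + self) the spiked city has the
  # largest local weighted sum, hence the maximal z
  wk <- build_weights(coords, scheme = "knn", k = 4, include_self = TRUE,
                      row_standardize = FALSE)
  spike <- rep(0, 16); spike[7] <- 10
  gi <- getis_ord_gi_star(spike, wk)
  # every neighbourhood containing the spike ties for the maximum
  expect_equal(gi$gi_star[7], max(gi$gi_star), tolerance = 1e-12)
  expect_gt(gi$gi_star[7], 0)
})

test_that("LISA labels respect alpha and flip with the field's sign", {
  lay <- generate_city_layout(60, "uniform", seed = 14)
  coords <- cbind(lay$u, lay$v)
  f <- simulate_clustered_field(coords, hot_centers = c(300, 300),
                                cold_centers = c(750, 750),
                                amplitude = 6, noise_sd = 0.1, seed = 8)
  w <- build_weights(coords)
  li <- local_moran(f, w, n_permutations = 499, alpha = 0.05, seed = 2)
  d_hot <- sqrt((coords[, 1] - 300)^2 + (coords[, 2] - 300)^2)
  expect_equal(as.character(li$label[which.min(d_hot)]), "HH")

  li0 <- local_moran(f, w, n_permutations = 499, alpha = 0, seed = 2)
  expect_true(all(li0$label == "not_significant"))

  # sign flip swaps HH with LL and HL with LH
  lin <- local_moran(-f, w, n_permutations = 499, alpha = 0.05, seed = 2)
  swap <- c(HH = "LL", LL = "HH", HL = "LH", LH = "HL",
            not_significant = "not_significant")
  expect_identical(as.character(lin$label),
                   unname(swap[as.character(li$label)]))
})

test_that("period comparison arithmetic and edge cases are exact", {
  expect_equal(moran_percent_change(0.2, 0.1), -50.0)
  expect_true(is.na(suppressMessages(moran_percent_change(0, 0.3))))

  lay <- generate_city_layout(40, "uniform", seed = 6)
  coords <- cbind(lay$u, lay$v)
  f <- simulate_clustered_field(coords, hot_centers = c(400, 400),
                                amplitude = 4, noise_sd = 0.2, seed = 3)
  panel <- rbind(
    data.frame(city_id = lay$city_id, u = lay$u, v = lay$v, year = 2012,
               birth_rate = f),
    data.frame(city_id = lay$city_id, u = lay$u, v = lay$v, year = 2017,
               birth_rate = f))
  res <- morans_i_by_period(panel, 2012, 2017, n_permutations = 99, seed = 1)
  expect_equal(res$percent_change, 0, tolerance = 1e-12)
  expect_error(morans_i_by_period(panel, 2012, 2012),
               class = "invalid_config")
})
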