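# Spatial weights construction.

test_that("knn ties break by id order and rows have exactly k neighbours", {
  pts <- rbind(c(0, 0), c(1, 0), c(2, 0))   # collinear, equally spaced
  w <- build_weights(pts, scheme = "knn", k = 1, row_standardize = FALSE)
  W <- as.matrix(w$W)
  expect_equal(W[2, ], c(1, 0, 0))          # middle point -> lower id
  expect_equal(unname(rowSums(W != 0)), rep(1, 3))

  set.seed(31)
  xy <- cbind(runif(15, 0, 100), runif(15, 0, 100))
  w5 <- build_weights(xy, scheme = "knn", k = 5, row_standardize = FALSE)
  expect_equal(unname(Matrix::rowSums(w5$W != 0)), rep(5, 15))
  expect_error(build_weights(xy, scheme = "knn", k = 15),
               class = "invalid_config")
})

test_that("row standardisation makes every non-empty row sum to one", {
  set.seed(8)
  xy <- cbind(runif(12, 0, 50), runif(12, 0, 50))
  for (scheme in c("inverse_distance", "knn", "distance_band")) {
    w <- build_weights(xy, scheme = scheme, k = 3)
    expect_equal(unname(Matrix::rowSums(w$W)), rep(1, 12), tolerance = 1e-12)
  }
})

test_that("an infinite band gives the complete directed graph", {
  set.seed(2)
  xy <- cbind(runif(5), runif(5))
  w <- build_weights(xy, scheme = "distance_band", band = Inf,
                     row_standardize = FALSE)
  expect_equal(Matrix::nnzero(w$W), 5 * 4)  # n(n-1) directed pairs
  expect_equal(unname(diag(as.matrix(w$W))), rep(0, 5))
})

test_that("self-inclusion and isolates behave as documented", {
  xy <- rbind(c(0, 0), c(1, 0), c(50, 50))
  expect_warning(
    w <- build_weights(xy, scheme = "distance_band", band = 2,
                       row_standardize = FALSE),
    class = "isolated_units")
  expect_equal(unname(Matrix::rowSums(w$W))[3], 0)

  ws <- build_weights(xy, scheme = "distance_band", band = 100,
                      include_self = TRUE, row_standardize = FALSE)
  expect_true(all(diag(as.matrix(ws$W)) == 1))
  expect_true(ws$includes_self)
})

test_that("the default band is the minimum-spanning-distance rule", {
  set.seed(5)
  xy <- cbind(runif(20, 0, 100), runif(20, 0, 100))
  d <- as.matrix(dist(xy)); diag(d) <- Inf
  expect_equal(critical_band(xy), max(apply(d, 1, min)))
  # no isolates under the default band
  expect_silent(w <- build_weights(xy))
  expect_true(all(Matrix::rowSums(w$W) > 0))
})

test_that("weights round-trip through the sparse triplet CSV", {
  set.seed(10)
  xy <- cbind(runif(8), runif(8))
  w <- build_weights(xy, scheme = "knn", k = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_weights(w, path)
  tr <- read_weights_triplets(path)
  W2 <- matrix(0, 8, 8)
  W2[cbind(tr$i, tr$j)] <- tr$w
  expect_equal(W2, unname(as.matrix(w$W)), tolerance = 1e-12)
})
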