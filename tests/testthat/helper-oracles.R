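# Brute-force reference implementations, written as literal formula
# evaluations (explicit double loops, explicit matrix inversion) and kept
# independent of the package's vectorised code paths.

bf_moran <- function(x, W) {
  W <- as.matrix(W)
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  s0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + W[i, j] * z[i] * z[j]
      s0 <- s0 + W[i, j]
    }
  }
  (n / s0) * num / sum(z^2)
}

bf_local_moran <- function(x, W) {
  W <- as.matrix(W)
  n <- length(x)
  z <- (x - mean(x)) / sqrt(sum((x - mean(x))^2) / n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lag <- 0
    for (j in seq_len(n)) lag <- lag + W[i, j] * z[j]
    out[i] <- z[i] * lag
  }
  out
}

bf_gi_star <- function(x, W) {
  W <- as.matrix(W)
  n <- length(x)
  xbar <- mean(x)
  S <- sqrt(sum(x^2) / n - xbar^2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    sw <- 0; sw2 <- 0; wx <- 0
    for (j in seq_len(n)) {
      sw <- sw + W[i, j]
      sw2 <- sw2 + W[i, j]^2
      wx <- wx + W[i, j] * x[j]
    }
    out[i] <- (wx - xbar * sw) / (S * sqrt((n * sw2 - sw^2) / (n - 1)))
  }
  out
}

# explicit normal equations (X' W X)^{-1} X' W y
bf_wls <- function(X, y, w) {
  X <- as.matrix(X)
  Wm <- diag(w, nrow = length(w))
  solve(t(X) %*% Wm %*% X) %*% t(X) %*% Wm %*% y
}

grid_coords <- function(k) {
  g <- expand.grid(u = seq_len(k), v = seq_len(k))
  as.matrix(g) * 10
}

# all pairwise euclidean distances, brute force
bf_pairwise_dists <- function(coords) {
  n <- nrow(coords)
  out <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      out <- c(out, sqrt(sum((coords[i, ] - coords[j, ])^2)))
    }
  }
  out
}
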