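# Global and local spatial autocorrelation statistics with permutation
# inference. Conventions: deviates are standardised by the population
# standard deviation (divisor n); permutation pseudo-p uses the +1
# correction, p = (1 + #{as-or-more extreme}) / (1 + n_permutations),
# with extremeness measured two-sided about the statistic's expectation.

drop_isolates <- function(values, w) {
  rs <- Matrix::rowSums(w$W != 0)
  cs <- Matrix::colSums(w$W != 0)
  if (w$includes_self) {
    rs <- Matrix::rowSums(w$W != 0) - 1
  }
  keep <- which(rs + cs > 0)
  if (length(keep) < w$n) {
    warn_gtwr("isolated_units",
              "excluding %d isolated unit(s) from the statistic",
              w$n - length(keep))
    values <- values[keep]
    w <- list(W = w$W[keep, keep, drop = FALSE], scheme = w$scheme,
              row_standardized = w$row_standardized,
              includes_self = w$includes_self, ids = w$ids[keep],
              n = length(keep), isolated = integer())
    class(w) <- "spatial_weights"
  }
  list(values = values, w = w, keep = keep)
}

#' Global Moran's I with analytic and permutation inference
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the
#' mean-deviates and `S0` the total weight. Expectation under the null is
#' `-1/(n-1)`; the analytic z-score uses the variance under the normality
#' assumption; the permutation p-value relabels the values over units.
#'
#' @param values numeric vector, one value per unit of `weights`.
#' @param weights a [build_weights()] object (self-weights excluded).
#' @param n_permutations number of random relabelings (0 disables).
#' @param seed integer seed for the permutations.
#' @return object of class `autocorr_test` with elements `statistic`,
#'   `expected_value`, `variance`, `z_score`, `p_analytic`,
#'   `p_permutation`, `n_permutations`, `seed`, `n`.
#' @export
morans_i <- function(values, weights, n_permutations = 999L, seed = 1L) {
  stopifnot(inherits(weights, "spatial_weights"))
  values <- as.numeric(values)
  if (length(values) != weights$n)
    stop_gtwr("invalid_config", "values length (%d) != number of units (%d)",
              length(values), weights$n)
  if (any(!is.finite(values)))
    stop_gtwr("invalid_config", "values contain non-finite entries")
  di <- drop_isolates(values, weights)
  values <- di$values
  W <- di$w$W
  n <- length(values)
  if (n < 3L) stop_gtwr("invalid_config", "need at least 3 non-isolated units")
  z <- values - mean(values)
  ss <- sum(z^2)
  if (ss == 0)
    stop_gtwr("degenerate_input",
              "values are constant: Moran's I undefined (zero variance)")
  S0 <- sum(W)
  I_of <- function(zz) (n / S0) * sum(zz * as.numeric(W %*% zz)) / ss
  I <- I_of(z)
  EI <- -1 / (n - 1)
  # variance under the normality assumption
  Wd <- as.matrix(W)
  S1 <- 0.5 * sum((Wd + t(Wd))^2)
  S2 <- sum((rowSums(Wd) + colSums(Wd))^2)
  VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  zsc <- (I - EI) / sqrt(VI)
  p_an <- 2 * stats::pnorm(-abs(zsc))
  p_perm <- NA_real_
  if (n_permutations > 0L) {
    perm_I <- with_seed(derive_seed(seed, "permute"),
      vapply(seq_len(n_permutations),
             function(b) I_of(z[sample.int(n)]), 0.0))
    p_perm <- (1 + sum(abs(perm_I - EI) >= abs(I - EI))) /
      (1 + n_permutations)
  }
  structure(list(statistic = I, expected_value = EI, variance = VI,
                 z_score = zsc, p_analytic = p_an, p_permutation = p_perm,
                 n_permutations = as.integer(n_permutations),
                 seed = seed, n = n, method = "Moran's I"),
            class = "autocorr_test")
}

#' @export
#' @method print autocorr_test
print.autocorr_test <- function(x, ...) {
  cat(sprintf("%s = %.4f (n = %d)\n", x$method, x$statistic, x$n))
  cat(sprintf("  E[I] = %.4f, z = %.3f, analytic p = %.4g",
              x$expected_value, x$z_score, x$p_analytic))
  if (!is.na(x$p_permutation))
    cat(sprintf(", permutation p = %.4g (%d perms)",
                x$p_permutation, x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Local Moran (LISA) with conditional permutation and cluster labels
#'
#' `I_i = z_i * sum_j w_ij z_j` with `z` the deviates standardised by the
#' population standard deviation. Inference is by conditional permutation:
#' unit `i`'s value is held fixed while its neighbours' values are drawn
#' without replacement from the remaining units. Quadrant labels: `HH` when
#' `z_i > 0` and the spatial lag of `z` at `i` is `> 0` (and the
#' permutation p is below `alpha`); `LL`, `HL`, `LH` analogously; otherwise
#' `not_significant`.
#'
#' @inheritParams morans_i
#' @param alpha significance level for labelling (raw pseudo-p by default).
#' @param p_adjust `"none"` (default) or `"BH"` for a Benjamini-Hochberg
#'   adjustment across units before labelling.
#' @return data.frame of class `lisa` with columns `id`, `value`,
#'   `local_i`, `z`, `lag_z`, `p_permutation`, `label`.
#' @export
local_moran <- function(values, weights, n_permutations = 999L,
                        alpha = 0.05, seed = 1L, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(inherits(weights, "spatial_weights"))
  values <- as.numeric(values)
  if (length(values) != weights$n)
    stop_gtwr("invalid_config", "values length (%d) != number of units (%d)",
              length(values), weights$n)
  di <- drop_isolates(values, weights)
  values <- di$values
  w <- di$w
  n <- length(values)
  if (n < 3L) stop_gtwr("invalid_config", "need at least 3 non-isolated units")
  sdev <- sqrt(mean((values - mean(values))^2))
  if (sdev == 0)
    stop_gtwr("degenerate_input",
              "values are constant: local Moran undefined (zero variance)")
  z <- (values - mean(values)) / sdev
  lag_z <- as.numeric(w$W %*% z)
  Ii <- z * lag_z
  p <- rep(NA_real_, n)
  Wmat <- w$W
  with_seed(derive_seed(seed, "permute"), {
    for (i in seq_len(n)) {
      nbr <- which(Wmat[i, ] != 0)
      nbr <- nbr[nbr != i]
      if (!length(nbr)) next
      wts <- as.numeric(Wmat[i, nbr])
      z_others <- z[-i]
      m <- length(z_others)
      k <- length(nbr)
      perm <- vapply(seq_len(n_permutations), function(b)
        z[i] * sum(wts * z_others[sample.int(m, k)]), 0.0)
      p[i] <- (1 + sum(abs(perm) >= abs(Ii[i]))) / (1 + n_permutations)
    }
  })
  p_lab <- if (p_adjust == "BH") stats::p.adjust(p, "BH") else p
  label <- rep("not_significant", n)
  sig <- !is.na(p_lab) & p_lab <= alpha
  label[sig & z > 0 & lag_z > 0] <- "HH"
  label[sig & z < 0 & lag_z < 0] <- "LL"
  label[sig & z > 0 & lag_z < 0] <- "HL"
  label[sig & z < 0 & lag_z > 0] <- "LH"
  out <- data.frame(id = w$ids, value = values, local_i = Ii, z = z,
                    lag_z = lag_z, p_permutation = p,
                    label = factor(label, levels = c("HH", "LL", "HL", "LH",
                                                     "not_significant")),
                    stringsAsFactors = FALSE)
  class(out) <- c("lisa", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "p_adjust") <- p_adjust
  out
}

#' Getis-Ord Gi* hot/cold-spot statistic
#'
#' The self-inclusive local sum statistic,
#' `Gi* = [sum_j w_ij x_j - xbar * sum_j w_ij] /
#'        (S * sqrt((n * sum_j w_ij^2 - (sum_j w_ij)^2) / (n - 1)))`
#' with `xbar` and `S` the global mean and (population) standard
#' deviation. Large positive z-scores mark clusters of high values (hot
#' spots), large negative ones clusters of low values (cold spots).
#' Categories apply the two-sided normal quantiles at 90/95/99%
#' confidence. A unit whose neighbourhood weights are uniform over all
#' units has a vanishing denominator and is assigned `z = 0` (its local
#' sum carries no information beyond the global mean).
#'
#' @param values numeric vector, one per unit.
#' @param weights a `spatial_weights` built with `include_self = TRUE`.
#' @return data.frame of class `hotspot` with columns `id`, `value`,
#'   `gi_star` (z-score), `category` (ordered factor `cold_99` ...
#'   `hot_99`).
#' @export
getis_ord_gi_star <- function(values, weights) {
  stopifnot(inherits(weights, "spatial_weights"))
  if (!weights$includes_self)
    stop_gtwr("invalid_config",
              "Gi* requires self-inclusive weights (include_self = TRUE)")
  values <- as.numeric(values)
  if (length(values) != weights$n)
    stop_gtwr("invalid_config", "values length (%d) != number of units (%d)",
              length(values), weights$n)
  n <- weights$n
  xbar <- mean(values)
  S <- sqrt(mean(values^2) - xbar^2)
  if (S == 0)
    stop_gtwr("degenerate_input",
              "values are constant: Gi* undefined (zero variance)")
  W <- weights$W
  wx <- as.numeric(W %*% values)
  sw <- Matrix::rowSums(W)
  sw2 <- Matrix::rowSums(W^2)
  den_inner <- (n * sw2 - sw^2) / (n - 1)
  z <- rep(0, n)
  ok <- den_inner > .Machine$double.eps * n
  z[ok] <- (wx[ok] - xbar * sw[ok]) / (S * sqrt(den_inner[ok]))
  q90 <- stats::qnorm(0.95); q95 <- stats::qnorm(0.975)
  q99 <- stats::qnorm(0.995)
  cats <- c("cold_99", "cold_95", "cold_90", "not_significant",
            "hot_90", "hot_95", "hot_99")
  category <- cut(z, breaks = c(-Inf, -q99, -q95, -q90, q90, q95, q99, Inf),
                  labels = cats, right = FALSE)
  # cut() with right = FALSE puts z exactly at a positive threshold into the
  # stronger class and at a negative threshold into the weaker; make the
  # negative side symmetric (|z| at the threshold counts as significant).
  category[z <= -q99] <- "cold_99"
  out <- data.frame(id = weights$ids, value = values, gi_star = z,
                    category = factor(as.character(category), levels = cats),
                    stringsAsFactors = FALSE)
  class(out) <- c("hotspot", "data.frame")
  out
}

#' Percent change between two Moran's I values
#'
#' `100 * (i_b - i_a) / i_a`; positive when autocorrelation increased.
#' Undefined (`NA`) when `i_a` is zero.
#'
#' @param i_a,i_b Moran's I in the earlier and later period.
#' @return percent change (scalar).
#' @export
moran_percent_change <- function(i_a, i_b) {
  if (!is.finite(i_a) || !is.finite(i_b))
    stop_gtwr("invalid_config", "both Moran's I values must be finite")
  if (i_a == 0) {
    message("Moran's I in the reference period is 0; percent change undefined")
    return(NA_real_)
  }
  100 * (i_b - i_a) / i_a
}

#' Moran's I before/after comparison between two year sets
#'
#' Aggregates the response to one value per city in each period (the
#' city's period mean by default), computes Moran's I on each period's
#' cross-section, and reports the percent change. With
#' `aggregate = "year_mean"` the annual Moran's I values within each
#' period are averaged instead.
#'
#' @param panel a panel data.frame with `city_id`, coordinate and year
#'   columns and the response.
#' @param period_a,period_b disjoint non-empty integer year sets.
#' @param response response column name.
#' @param coords coordinate column names.
#' @param time year column name.
#' @param aggregate `"city_mean"` (default) or `"year_mean"`.
#' @param weights_args list of arguments forwarded to [build_weights()].
#' @param n_permutations,seed permutation settings per [morans_i()].
#' @return list with `moran_a`, `moran_b` (per-period results), `I_a`,
#'   `I_b`, `percent_change`.
#' @export
morans_i_by_period <- function(panel, period_a, period_b,
                               response = "birth_rate",
                               coords = c("u", "v"), time = "year",
                               aggregate = c("city_mean", "year_mean"),
                               weights_args = list(),
                               n_permutations = 999L, seed = 1L) {
  aggregate <- match.arg(aggregate)
  period_a <- as.integer(period_a); period_b <- as.integer(period_b)
  if (!length(period_a) || !length(period_b))
    stop_gtwr("invalid_config", "both periods must be non-empty")
  if (length(intersect(period_a, period_b)))
    stop_gtwr("invalid_config", "periods must be disjoint")
  one_period <- function(years, seed_off) {
    sub <- panel[panel[[time]] %in% years, , drop = FALSE]
    if (!nrow(sub)) stop_gtwr("invalid_config", "a period selects no records")
    if (aggregate == "city_mean") {
      agg <- stats::aggregate(sub[, c(response, coords)],
                              by = list(city_id = sub$city_id), FUN = mean)
      w <- do.call(build_weights, c(list(coords = agg[, coords]),
                                    weights_args))
      morans_i(agg[[response]], w, n_permutations = n_permutations,
               seed = seed + seed_off)
    } else {
      res <- lapply(sort(unique(sub[[time]])), function(yr) {
        s <- sub[sub[[time]] == yr, , drop = FALSE]
        w <- do.call(build_weights, c(list(coords = s[, coords]),
                                      weights_args))
        morans_i(s[[response]], w, n_permutations = n_permutations,
                 seed = seed + seed_off + yr %% 1000L)
      })
      I_mean <- mean(vapply(res, `[[`, 0.0, "statistic"))
      structure(list(statistic = I_mean, expected_value = NA_real_,
                     variance = NA_real_, z_score = NA_real_,
                     p_analytic = NA_real_, p_permutation = NA_real_,
                     n_permutations = n_permutations, seed = seed,
                     n = nrow(sub), method = "Moran's I (annual mean)",
                     annual = res),
                class = "autocorr_test")
    }
  }
  ma <- one_period(period_a, 0L)
  mb <- one_period(period_b, 500L)
  list(moran_a = ma, moran_b = mb,
       I_a = ma$statistic, I_b = mb$statistic,
       percent_change = moran_percent_change(ma$statistic, mb$statistic))
}
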