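# Geographically and temporally weighted regression: spatiotemporal kernel
# weights, leave-one-out CV bandwidth calibration, pointwise weighted least
# squares, and fit diagnostics. The whole module is deterministic.

#' Squared space-time distance
#'
#' `d^2 = lambda * ((u_i - u_j)^2 + (v_i - v_j)^2) + mu * (t_i - t_j)^2`,
#' the additive quadratic combination of spatial and temporal separation.
#' Only the ratio `tau = mu / lambda` is identifiable jointly with the
#' kernel bandwidth, so model fitting fixes `lambda = 1` and calibrates
#' `tau`.
#'
#' @param p,q space-time points as length-3 numeric vectors `(u, v, t)` or
#'   matrices with columns `u`, `v`, `t`.
#' @param lambda spatial scale factor (> 0).
#' @param mu temporal scale factor (>= 0).
#' @return non-negative squared distance(s).
#' @export
#' @examples
#' st_distance_sq(c(0, 0, 2012), c(3, 4, 2012))            # 25
#' st_distance_sq(c(0, 0, 0), c(1, 3, 3), lambda = 0.5, mu = 2)  # 23
st_distance_sq <- function(p, q, lambda = 1, mu = 0) {
  if (lambda <= 0) stop_gtwr("invalid_config", "lambda must be positive")
  if (mu < 0) stop_gtwr("invalid_config", "mu must be non-negative")
  p <- if (is.null(dim(p))) matrix(p, ncol = 3) else as.matrix(p)
  q <- if (is.null(dim(q))) matrix(q, ncol = 3) else as.matrix(q)
  lambda * ((p[, 1] - q[, 1])^2 + (p[, 2] - q[, 2])^2) +
    mu * (p[, 3] - q[, 3])^2
}

#' Specify a spatiotemporal kernel
#'
#' @param family `"gaussian"` (weights strictly positive everywhere) or
#'   `"bisquare"` (compact support: zero beyond the bandwidth).
#' @param bandwidth kernel scale `h` (> 0); with `adaptive = TRUE`,
#'   interpreted as a neighbour count and converted per focal point to the
#'   combined distance of its `h`-th nearest observation.
#' @param lambda spatial scale factor (fixed at 1 in fitting).
#' @param mu temporal scale factor; `mu = 0` is purely spatial weighting
#'   (the GWR degenerate case).
#' @param adaptive logical; fixed bandwidth by default.
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("gaussian", "bisquare"), bandwidth,
                        lambda = 1, mu = 0, adaptive = FALSE) {
  family <- match.arg(family)
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L || bandwidth <= 0)
    stop_gtwr("invalid_config", "bandwidth must be a positive scalar")
  if (lambda <= 0) stop_gtwr("invalid_config", "lambda must be positive")
  if (mu < 0) stop_gtwr("invalid_config", "mu must be non-negative")
  structure(list(family = family, bandwidth = bandwidth, lambda = lambda,
                 mu = mu, adaptive = isTRUE(adaptive)),
            class = "kernel_spec")
}

#' @export
#' @method print kernel_spec
print.kernel_spec <- function(x, ...) {
  cat(sprintf("%s kernel, %s bandwidth h = %.6g, tau = mu/lambda = %.6g\n",
              x$family, if (x$adaptive) "adaptive" else "fixed",
              x$bandwidth, x$mu / x$lambda))
  invisible(x)
}

#' Kernel weight from squared distance
#'
#' Gaussian: `exp(-d^2 / h^2)`. Bisquare: `(1 - d^2 / h^2)^2` when
#' `d < h`, else 0.
#'
#' @param d_sq non-negative squared distance(s).
#' @param spec a [kernel_spec()] (or list with `family` and `bandwidth`).
#' @return weights in `[0, 1]`.
#' @export
kernel_weight <- function(d_sq, spec) {
  h2 <- spec$bandwidth^2
  if (spec$family == "gaussian") {
    exp(-d_sq / h2)
  } else {
    w <- (1 - d_sq / h2)^2
    w[d_sq >= h2] <- 0
    w
  }
}

#' Local weighted least squares at one fit point
#'
#' Solves `beta = (X' W X)^{-1} X' W y` with `W = diag(w)` via the
#' Cholesky factorisation of the weighted cross-product. A near-singular
#' system receives a ridge of `1e-8 * mean(diag(X'WX))` on the diagonal;
#' if it is still singular a `singular_fit` error is raised.
#'
#' @param X design matrix (intercept column included).
#' @param y response vector.
#' @param w non-negative weights.
#' @param point_id identifier used in error messages.
#' @return named coefficient vector.
#' @export
fit_pointwise <- function(X, y, w, point_id = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (sum(w > 0) < p)
    stop_gtwr("underdetermined_fit",
              "fewer positive weights (%d) than parameters (%d)%s",
              sum(w > 0), p, if (is.null(point_id)) "" else
                sprintf(" at observation %s", point_id))
  A <- crossprod(X, X * w)
  b <- crossprod(X, w * y)
  sol <- solve_spd_ridge(A, b, point_id)
  beta <- drop(sol$coef)
  names(beta) <- colnames(X)
  beta
}

# Cholesky solve with ridge fallback; returns coefficients and the
# Cholesky factor for reuse (hat values).
solve_spd_ridge <- function(A, b, point_id = NULL) {
  if (any(!is.finite(A)))
    stop_gtwr("singular_fit",
              "weighted design is not finite%s",
              if (is.null(point_id)) "" else
                sprintf(" at observation %s", point_id))
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) {
    A <- A + diag(1e-8 * mean(diag(A)) + 1e-300, ncol(A))
    R <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(R))
      stop_gtwr("singular_fit",
                "weighted design is rank deficient%s",
                if (is.null(point_id)) "" else
                  sprintf(" at observation %s", point_id))
  }
  list(coef = backsolve(R, backsolve(R, b, transpose = TRUE)), R = R)
}

# --- internal fitting engine -------------------------------------------------

# Precompute spatial and temporal squared-distance matrices.
st_dist_matrices <- function(u, v, tt) {
  D2s <- outer(u, u, "-")^2 + outer(v, v, "-")^2
  D2t <- outer(tt, tt, "-")^2
  list(D2s = D2s, D2t = D2t)
}

# Adaptive bandwidth: per-focal distance to the h-th nearest observation
# (self included) in the combined metric.
adaptive_h2 <- function(d2, k) {
  k <- max(2L, min(as.integer(k), length(d2)))
  sort(d2, partial = k)[k]
}

# One full pass over fit points. loo = TRUE zeroes the self-weight and
# returns only LOO predictions (Inf score contribution when a point is
# isolated under a compact kernel).
gtwr_engine <- function(X, y, D2, family, h, adaptive = FALSE,
                        future_mask = NULL, loo = FALSE, ids = NULL) {
  n <- nrow(X); p <- ncol(X)
  h2 <- h^2
  if (loo) {
    pred <- numeric(n)
    for (i in seq_len(n)) {
      d2 <- D2[i, ]
      hi2 <- if (adaptive) adaptive_h2(d2, h) else h2
      w <- if (family == "gaussian") exp(-d2 / hi2) else {
        wi <- (1 - d2 / hi2)^2; wi[d2 >= hi2] <- 0; wi
      }
      w[i] <- 0
      if (!is.null(future_mask)) w[future_mask[[i]]] <- 0
      if (sum(w > 0) < p) return(list(cv = Inf))
      A <- crossprod(X, X * w)
      b <- crossprod(X, w * y)
      sol <- tryCatch(solve_spd_ridge(A, b), error = function(e) NULL)
      if (is.null(sol)) return(list(cv = Inf))
      pred[i] <- sum(X[i, ] * sol$coef)
    }
    return(list(cv = sum((y - pred)^2), pred = pred))
  }
  beta <- matrix(NA_real_, n, p, dimnames = list(NULL, colnames(X)))
  fitted <- numeric(n)
  s_ii <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- D2[i, ]
    hi2 <- if (adaptive) adaptive_h2(d2, h) else h2
    w <- if (family == "gaussian") exp(-d2 / hi2) else {
      wi <- (1 - d2 / hi2)^2; wi[d2 >= hi2] <- 0; wi
    }
    if (!is.null(future_mask)) w[future_mask[[i]]] <- 0
    id_i <- if (is.null(ids)) i else ids[i]
    if (sum(w > 0) < p)
      stop_gtwr("underdetermined_fit",
                "fewer positive weights than parameters at observation %s",
                id_i)
    A <- crossprod(X, X * w)
    b <- crossprod(X, w * y)
    sol <- solve_spd_ridge(A, b, id_i)
    beta[i, ] <- sol$coef
    fitted[i] <- sum(X[i, ] * sol$coef)
    xi <- backsolve(sol$R, backsolve(sol$R, X[i, ], transpose = TRUE))
    s_ii[i] <- w[i] * sum(X[i, ] * xi)
  }
  list(beta = beta, fitted = fitted, s_ii = s_ii)
}

# Resolve formula/data/coords/time into the fitting ingredients.
gtwr_ingredients <- function(formula, data, coords, time) {
  for (cn in c(coords, time))
    if (!cn %in% names(data))
      stop_gtwr("invalid_config", "column '%s' not found in data", cn)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (!"(Intercept)" %in% colnames(X))
    stop_gtwr("invalid_config", "the model must include an intercept")
  u <- as.numeric(data[[coords[1]]])
  v <- as.numeric(data[[coords[2]]])
  tt <- as.numeric(data[[time]])
  if (any(!is.finite(c(u, v, tt))))
    stop_gtwr("invalid_config", "coordinates and times must be finite")
  tc <- tt - mean(tt)   # centre time so tau * dt^2 is well scaled
  ids <- if ("city_id" %in% names(data)) data$city_id else seq_len(nrow(X))
  list(X = X, y = as.numeric(y), u = u, v = v, t_raw = tt, t = tc,
       ids = ids, terms = attr(mf, "terms"))
}

# Default tau grid: a unit-free raw grid scaled by the squared ratio of
# spatial to temporal extent, so temporal separation can actually compete
# with spatial separation whatever the coordinate units.
default_tau_grid <- function(u, v, tt) {
  raw <- c(0, 0.25, 0.5, 1, 2, 4, 8)
  t_ext <- diff(range(tt))
  if (t_ext == 0) return(0)
  s_ext <- sqrt(diff(range(u))^2 + diff(range(v))^2)
  raw * (s_ext / t_ext)^2
}

#' Leave-one-out cross-validation score of a GTWR specification
#'
#' For each observation the local fit is recomputed with its own weight
#' forced to zero and the squared prediction errors are summed. An
#' observation left with fewer positive weights than parameters (possible
#' under the compact bisquare kernel) makes the score infinite; it is
#' never silently dropped.
#'
#' @inheritParams gtwr
#' @param bandwidth kernel bandwidth `h`.
#' @param tau temporal-vs-spatial squared-distance ratio (`mu / lambda`).
#' @return non-negative scalar (possibly `Inf`).
#' @export
cv_score <- function(formula, data, coords = c("u", "v"), time = "year",
                     bandwidth, tau = 0,
                     kernel = c("gaussian", "bisquare"),
                     adaptive = FALSE, causal = FALSE) {
  kernel <- match.arg(kernel)
  ing <- gtwr_ingredients(formula, data, coords, time)
  dm <- st_dist_matrices(ing$u, ing$v, ing$t)
  D2 <- dm$D2s + tau * dm$D2t
  fm <- if (causal) future_mask_list(ing$t) else NULL
  gtwr_engine(ing$X, ing$y, D2, kernel, bandwidth, adaptive = adaptive,
              future_mask = fm, loo = TRUE)$cv
}

future_mask_list <- function(tt) lapply(seq_along(tt), function(i)
  which(tt > tt[i]))

golden_section <- function(f, lo, hi, tol = 1e-3, max_iter = 80L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  trace <- data.frame(x = c(x1, x2), fx = c(f1, f2))
  iter <- 0L
  while (b - a > tol && iter < max_iter) {
    if (f1 <= f2) { b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
      trace <- rbind(trace, data.frame(x = x1, fx = f1))
    } else { a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
      trace <- rbind(trace, data.frame(x = x2, fx = f2))
    }
    iter <- iter + 1L
  }
  xb <- if (f1 <= f2) x1 else x2
  list(x = xb, fx = min(f1, f2), converged = (b - a) <= tol, trace = trace)
}

#' Calibrate GTWR bandwidth and space-time ratio by cross-validation
#'
#' For each candidate `tau` the bandwidth `h` is optimised by
#' golden-section search on `log h`, bracketed between the smallest
#' non-zero and twice the largest pairwise combined distance; the
#' `(tau, h)` pair with the smallest leave-one-out CV score wins. The
#' search is deterministic.
#'
#' @inheritParams gtwr
#' @param tau_grid candidate `tau` values; `NULL` for the default
#'   extent-scaled grid.
#' @param tol convergence tolerance on `log h`.
#' @return list with `bandwidth`, `tau`, `cv`, `converged`, and the
#'   per-`tau` search `trace`.
#' @export
gtwr_bandwidth <- function(formula, data, coords = c("u", "v"),
                           time = "year",
                           kernel = c("gaussian", "bisquare"),
                           tau_grid = NULL, adaptive = FALSE,
                           causal = FALSE, tol = 1e-3) {
  kernel <- match.arg(kernel)
  ing <- gtwr_ingredients(formula, data, coords, time)
  dm <- st_dist_matrices(ing$u, ing$v, ing$t)
  if (is.null(tau_grid)) tau_grid <- default_tau_grid(ing$u, ing$v, ing$t)
  if (!length(tau_grid)) stop_gtwr("invalid_config", "tau_grid is empty")
  fm <- if (causal) future_mask_list(ing$t) else NULL
  best <- NULL
  traces <- list()
  for (tau in tau_grid) {
    D2 <- dm$D2s + tau * dm$D2t
    pos <- D2[D2 > 0]
    if (!length(pos))
      stop_gtwr("degenerate_input", "all observations are coincident")
    lo <- log(sqrt(min(pos))); hi <- log(2 * sqrt(max(pos)))
    if (adaptive) { lo <- log(ncol(ing$X) + 1); hi <- log(nrow(ing$X)) }
    f <- function(lh) gtwr_engine(ing$X, ing$y, D2, kernel, exp(lh),
                                  adaptive = adaptive, future_mask = fm,
                                  loo = TRUE)$cv
    gs <- golden_section(f, lo, hi, tol = tol)
    traces[[as.character(tau)]] <- transform(gs$trace, tau = tau,
                                             h = exp(x))
    if (is.null(best) || gs$fx < best$cv)
      best <- list(bandwidth = exp(gs$x), tau = tau, cv = gs$fx,
                   converged = gs$converged)
  }
  c(best, list(trace = do.call(rbind, traces)))
}

#' Fit a geographically and temporally weighted regression
#'
#' Every observation receives its own coefficient vector, estimated by
#' weighted least squares with kernel weights decaying in the combined
#' space-time distance
#' `d_ij^2 = (u_i-u_j)^2 + (v_i-v_j)^2 + tau * (t_i-t_j)^2`. `tau = 0`
#' recovers a purely spatial GWR; as the bandwidth grows every local fit
#' converges to the global OLS fit. When `bandwidth` (and/or `tau`) is
#' `NULL` it is calibrated by leave-one-out cross-validation via
#' [gtwr_bandwidth()]. Time enters as a real-valued coordinate, centred
#' internally. Temporal weighting is symmetric by default; `causal = TRUE`
#' restricts each local fit to past-or-present observations.
#'
#' Diagnostics follow the GWR conventions: the hat trace `tr(S)` (with
#' `S` the matrix mapping `y` to fitted values) is the effective number of
#' parameters; `adjusted R^2 = 1 - (RSS/(n - tr(S))) / (TSS/(n - 1))`;
#' `AICc = 2n log(sigma_hat) + n log(2 pi) + n (n + tr(S)) /
#' (n - 2 - tr(S))`.
#'
#' @param formula model formula, e.g. `birth_rate ~ pgdp + ur + hp`.
#' @param data data.frame containing the model variables plus coordinate
#'   and time columns.
#' @param coords names of the planar coordinate columns. Projected planar
#'   units are required; project lon/lat before fitting.
#' @param time name of the (real-valued) time column.
#' @param bandwidth kernel bandwidth `h`; `NULL` to calibrate by CV.
#' @param tau temporal/spatial squared-distance ratio; `NULL` to calibrate
#'   over `tau_grid`.
#' @param kernel `"gaussian"` (default; never-zero weights avoid
#'   isolation) or `"bisquare"`.
#' @param tau_grid candidate `tau` values for calibration; `NULL` for the
#'   extent-scaled default grid.
#' @param adaptive interpret the bandwidth as a neighbour count?
#' @param causal restrict local fits to past-or-present observations?
#' @param verbose print calibration progress?
#' @return object of class `gtwr`; see [summary.gtwr()], [coef.gtwr()],
#'   [predict.gtwr()].
#' @export
#' @examples
#' cfg <- synthetic_config(n_cities = 40, years = 2012:2015, seed = 3,
#'                         missing_rate = 0)
#' panel <- simulate_panel(cfg)
#' fit <- gtwr(birth_rate ~ pgdp + hp + fee, panel, bandwidth = 300, tau = 0)
#' fit
gtwr <- function(formula, data, coords = c("u", "v"), time = "year",
                 bandwidth = NULL, tau = NULL,
                 kernel = c("gaussian", "bisquare"), tau_grid = NULL,
                 adaptive = FALSE, causal = FALSE, verbose = FALSE) {
  kernel <- match.arg(kernel)
  cl <- match.call()
  ing <- gtwr_ingredients(formula, data, coords, time)
  n <- nrow(ing$X); p <- ncol(ing$X)
  if (n <= p + 1L)
    stop_gtwr("invalid_config", "need n > k + 1 observations (n=%d, k+1=%d)",
              n, p)
  search <- NULL
  cvs <- NA_real_
  if (is.null(bandwidth)) {
    if (is.null(tau_grid) && !is.null(tau)) tau_grid <- tau
    search <- gtwr_bandwidth(formula, data, coords = coords, time = time,
                             kernel = kernel, tau_grid = tau_grid,
                             adaptive = adaptive, causal = causal)
    bandwidth <- search$bandwidth
    tau <- search$tau
    cvs <- search$cv
    if (verbose)
      message(sprintf("CV-selected h = %.4g, tau = %.4g (CV = %.6g)",
                      bandwidth, tau, cvs))
  } else if (is.null(tau)) {
    if (is.null(tau_grid))
      tau_grid <- default_tau_grid(ing$u, ing$v, ing$t)
    scores <- vapply(tau_grid, function(tg)
      cv_score(formula, data, coords, time, bandwidth = bandwidth,
               tau = tg, kernel = kernel, adaptive = adaptive,
               causal = causal), 0.0)
    tau <- tau_grid[which.min(scores)]
    cvs <- min(scores)
  }
  dm <- st_dist_matrices(ing$u, ing$v, ing$t)
  D2 <- dm$D2s + tau * dm$D2t
  fm <- if (causal) future_mask_list(ing$t) else NULL
  eng <- gtwr_engine(ing$X, ing$y, D2, kernel, bandwidth,
                     adaptive = adaptive, future_mask = fm, ids = ing$ids)
  resid <- ing$y - eng$fitted
  rss <- sum(resid^2)
  tss <- sum((ing$y - mean(ing$y))^2)
  trS <- sum(eng$s_ii)
  adj_r2 <- 1 - (rss / (n - trS)) / (tss / (n - 1))
  sigma <- sqrt(rss / n)
  aicc <- 2 * n * log(sigma) + n * log(2 * pi) +
    n * (n + trS) / (n - 2 - trS)
  if (is.na(cvs))
    cvs <- gtwr_engine(ing$X, ing$y, D2, kernel, bandwidth,
                       adaptive = adaptive, future_mask = fm, loo = TRUE)$cv
  structure(list(
    coefficients = eng$beta, fitted = eng$fitted, residuals = resid,
    y = ing$y, hat_trace = trS, adj_r2 = adj_r2, aicc = aicc,
    cv_score = cvs, rss = rss, tss = tss, sigma = sigma,
    kernel = kernel_spec(kernel, bandwidth, lambda = 1, mu = tau,
                         adaptive = adaptive),
    tau = tau, causal = causal,
    variable_names = colnames(ing$X),
    points = data.frame(id = ing$ids, u = ing$u, v = ing$v,
                        t = ing$t_raw, stringsAsFactors = FALSE),
    X = ing$X, terms = ing$terms, formula = formula, call = cl,
    coords = coords, time = time, n = n, p = p,
    search = search), class = "gtwr")
}

#' Ordinary least squares baseline fit
#'
#' The global-coefficient baseline for GTWR, via [stats::lm()]. Supplies
#' the coefficient standard errors consumed by [nonstationarity_test()].
#'
#' @inheritParams gtwr
#' @return object of class `ols_fit`: list with the underlying `lm`
#'   object, `coefficients`, `se`, `adj_r2`, `variable_names`.
#' @export
fit_ols <- function(formula, data) {
  m <- stats::lm(formula, data)
  qrr <- qr(stats::model.matrix(m))
  if (qrr$rank < ncol(stats::model.matrix(m)))
    stop_gtwr("singular_fit", "OLS design matrix is rank deficient")
  sm <- summary(m)
  structure(list(model = m, coefficients = stats::coef(m),
                 se = sm$coefficients[, "Std. Error"],
                 adj_r2 = sm$adj.r.squared,
                 variable_names = names(stats::coef(m))),
            class = "ols_fit")
}

#' @export
#' @method print ols_fit
print.ols_fit <- function(x, ...) {
  cat("OLS baseline fit\n")
  print(data.frame(estimate = x$coefficients, se = x$se))
  cat(sprintf("Adjusted R-squared: %.4f\n", x$adj_r2))
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) object$coefficients

#' Spatiotemporal non-stationarity test (IQR vs 2 SE)
#'
#' A variable's coefficient is flagged as non-stationary when the
#' interquartile range of its local GTWR estimates strictly exceeds twice
#' its OLS standard error. Quartiles use linear interpolation
#' ([stats::quantile()] type 7). The intercept is excluded by default
#' (the comparison targets the substantive covariates).
#'
#' @param gtwr_fit a [gtwr()] fit.
#' @param ols_fit a [fit_ols()] fit on the same variables.
#' @param include_intercept also test the intercept?
#' @return data.frame of class `nonstationarity_report` with columns
#'   `variable`, `iqr_gtwr`, `two_se_ols`, `nonstationary`.
#' @export
nonstationarity_test <- function(gtwr_fit, ols_fit,
                                 include_intercept = FALSE) {
  stopifnot(inherits(gtwr_fit, "gtwr"), inherits(ols_fit, "ols_fit"))
  vars <- intersect(gtwr_fit$variable_names, ols_fit$variable_names)
  if (!setequal(gtwr_fit$variable_names, ols_fit$variable_names))
    stop_gtwr("invalid_config",
              "GTWR and OLS fits must share the same variables")
  if (!include_intercept) vars <- setdiff(vars, "(Intercept)")
  iqr <- vapply(vars, function(vn) {
    q <- stats::quantile(gtwr_fit$coefficients[, vn], c(0.25, 0.75),
                         type = 7, names = FALSE)
    q[2] - q[1]
  }, 0.0)
  two_se <- 2 * ols_fit$se[vars]
  out <- data.frame(variable = vars, iqr_gtwr = unname(iqr),
                    two_se_ols = unname(two_se),
                    nonstationary = unname(iqr) > unname(two_se),
                    stringsAsFactors = FALSE)
  class(out) <- c("nonstationarity_report", "data.frame")
  out
}
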