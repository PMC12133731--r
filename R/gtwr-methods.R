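# S3 methods for fitted GTWR models.

#' @export
#' @method print gtwr
print.gtwr <- function(x, ...) {
  cat("Geographically and temporally weighted regression\n")
  cat("Call: "); print(x$call)
  cat(sprintf("n = %d observations, %d local coefficients each\n",
              x$n, x$p))
  print(x$kernel)
  cat(sprintf("Effective parameters tr(S) = %.2f\n", x$hat_trace))
  cat(sprintf("Adjusted R-squared: %.4f   AICc: %.2f   CV score: %.6g\n",
              x$adj_r2, x$aicc, x$cv_score))
  invisible(x)
}

#' Coefficient distribution summary of a GTWR fit
#'
#' Six order statistics (mean, minimum, lower quartile, median, upper
#' quartile, maximum) of the local coefficients of each model term, the
#' standard summary table for locally varying coefficient models.
#' Quartiles use linear interpolation (type 7).
#'
#' @param object a [gtwr()] fit.
#' @param ... unused.
#' @return object of class `summary.gtwr`: a data.frame with columns
#'   `variable`, `avg`, `min`, `lq`, `med`, `uq`, `max`, with the model
#'   diagnostics as attributes.
#' @export
#' @method summary gtwr
summary.gtwr <- function(object, ...) {
  b <- object$coefficients
  qs <- t(apply(b, 2L, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1),
                type = 7, names = FALSE))
  out <- data.frame(variable = colnames(b), avg = colMeans(b),
                    min = qs[, 1], lq = qs[, 2], med = qs[, 3],
                    uq = qs[, 4], max = qs[, 5],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "adj_r2") <- object$adj_r2
  attr(out, "aicc") <- object$aicc
  attr(out, "hat_trace") <- object$hat_trace
  attr(out, "kernel") <- object$kernel
  attr(out, "n") <- object$n
  class(out) <- c("summary.gtwr", "data.frame")
  out
}

#' @export
#' @method print summary.gtwr
print.summary.gtwr <- function(x, digits = 6, ...) {
  cat("GTWR local coefficient summary\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], signif, digits = digits)
  print(df, row.names = FALSE)
  cat(sprintf("Adjusted R-squared: %.6g (n = %d, tr(S) = %.2f)\n",
              attr(x, "adj_r2"), attr(x, "n"), attr(x, "hat_trace")))
  invisible(x)
}

#' @export
coef.gtwr <- function(object, ...) object$coefficients

#' @export
fitted.gtwr <- function(object, ...) object$fitted

#' @export
residuals.gtwr <- function(object, ...) object$residuals

#' Predict from a GTWR fit at new space-time points
#'
#' Local coefficients at each new point are estimated from the training
#' observations with the fitted kernel, then applied to the new
#' covariates.
#'
#' @param object a [gtwr()] fit.
#' @param newdata data.frame with the model covariates plus coordinate and
#'   time columns (same names as in training).
#' @param coefficients return the local coefficient matrix instead of
#'   predictions?
#' @param ... unused.
#' @return numeric vector of predictions (or a coefficient matrix).
#' @export
predict.gtwr <- function(object, newdata, coefficients = FALSE, ...) {
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, na.action = stats::na.fail)
  Xn <- stats::model.matrix(tt, mf)
  un <- as.numeric(newdata[[object$coords[1]]])
  vn <- as.numeric(newdata[[object$coords[2]]])
  tn <- as.numeric(newdata[[object$time]]) - mean(object$points$t)
  tr_t <- object$points$t - mean(object$points$t)
  spec <- object$kernel
  m <- nrow(Xn)
  beta <- matrix(NA_real_, m, object$p,
                 dimnames = list(NULL, object$variable_names))
  for (i in seq_len(m)) {
    d2 <- (object$points$u - un[i])^2 + (object$points$v - vn[i])^2 +
      object$tau * (tr_t - tn[i])^2
    hi2 <- if (spec$adaptive) adaptive_h2(d2, spec$bandwidth) else
      spec$bandwidth^2
    w <- if (spec$family == "gaussian") exp(-d2 / hi2) else {
      wi <- (1 - d2 / hi2)^2; wi[d2 >= hi2] <- 0; wi
    }
    if (object$causal) w[tr_t > tn[i]] <- 0
    beta[i, ] <- fit_pointwise(object$X, object$y, w, point_id = i)
  }
  if (coefficients) return(beta)
  unname(rowSums(Xn * beta))
}

#' Simulate responses from a fitted GTWR model
#'
#' Draws `nsim` response vectors as fitted values plus iid Gaussian noise
#' at the fit's residual standard deviation.
#'
#' @param object a [gtwr()] fit.
#' @param nsim number of simulated response vectors.
#' @param seed integer seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns.
#' @export
simulate.gtwr <- function(object, nsim = 1, seed = NULL, ...) {
  out <- with_seed(seed, {
    as.data.frame(replicate(nsim, object$fitted +
                              stats::rnorm(object$n, 0, object$sigma)))
  })
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot local coefficients of a GTWR fit over space
#'
#' A base-graphics map: fit points coloured by the local coefficient of
#' one model term (averaged over years at each location).
#'
#' @param x a [gtwr()] fit.
#' @param variable model term to display (default: first covariate).
#' @param ... passed to [graphics::plot()].
#' @export
plot.gtwr <- function(x, variable = NULL, ...) {
  if (is.null(variable))
    variable <- setdiff(x$variable_names, "(Intercept)")[1]
  if (!variable %in% x$variable_names)
    stop_gtwr("invalid_config", "unknown variable '%s'; available: %s",
              variable, paste(x$variable_names, collapse = ", "))
  agg <- stats::aggregate(x$coefficients[, variable],
                          by = list(u = x$points$u, v = x$points$v),
                          FUN = mean)
  pal <- grDevices::hcl.colors(11, "Blue-Red 3", rev = TRUE)
  brk <- cut(agg$x, breaks = 11)
  graphics::plot(agg$u, agg$v, col = pal[as.integer(brk)], pch = 16,
                 xlab = "u", ylab = "v",
                 main = sprintf("Local coefficient: %s", variable), ...)
  invisible(agg)
}

#' Export a GTWR fit as a long-format table
#'
#' One row per observation: identifiers, coordinates, year, every local
#' coefficient, fitted value and residual. Report tables
#' ([summarize_coefficients()], [phase_comparison()], [temporal_trend()],
#' [coefficient_map()]) are pure functions of this table.
#'
#' @param x a [gtwr()] fit.
#' @param ... unused.
#' @return data.frame.
#' @export
as.data.frame.gtwr <- function(x, ...) {
  b <- as.data.frame(x$coefficients)
  names(b) <- sub("^\\(Intercept\\)$", "intercept", names(b))
  cbind(data.frame(city_id = x$points$id, u = x$points$u, v = x$points$v,
                   year = x$points$t, stringsAsFactors = FALSE),
        b, fitted = x$fitted, residual = x$residuals)
}

#' @export
#' @method print nonstationarity_report
print.nonstationarity_report <- function(x, ...) {
  cat("Non-stationarity test: IQR of local coefficients vs 2 x OLS SE\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
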