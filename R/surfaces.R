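#' Specify a space-time coefficient surface
#'
#' A surface describes how a regression coefficient varies over planar space
#' and time. Surfaces are the ground truth of the synthetic panel generator:
#' [simulate_panel()] evaluates one surface per model term at every
#' city-year and records the value, so that downstream fits can be scored
#' for parameter recovery.
#'
#' Available kinds:
#' \describe{
#'   \item{`constant`}{`base_value` everywhere.}
#'   \item{`linear_space`}{`base_value + amplitude * ((u - cu) + (v - cv)) /
#'     length_scale`, a planar ramp through `center`.}
#'   \item{`gaussian_bump`}{`base_value + amplitude *
#'     exp(-d^2 / (2 * length_scale^2))` with `d` the distance to `center`.}
#'   \item{`linear_time`}{`base_value + time_slope * (t - t0)` where `t0` is
#'     the first year of the panel.}
#'   \item{`separable_product`}{the `gaussian_bump` spatial factor multiplied
#'     by the temporal factor `1 + time_slope * (t - t0)`.}
#' }
#'
#' @param kind surface family; one of `"constant"`, `"linear_space"`,
#'   `"gaussian_bump"`, `"linear_time"`, `"separable_product"`.
#' @param base_value baseline coefficient level.
#' @param amplitude spatial deviation scale (ignored by `constant` and
#'   `linear_time`).
#' @param center numeric length-2, the `(u, v)` centre of spatial variation.
#' @param length_scale positive spatial scale in coordinate units.
#' @param time_slope change in the coefficient per year.
#' @return an object of class `surface_spec`.
#' @seealso [evaluate_surface()], [simulate_panel()]
#' @export
#' @examples
#' sp <- surface_spec("gaussian_bump", base_value = 0, amplitude = 2,
#'                    center = c(500, 500), length_scale = 200)
#' evaluate_surface(sp, u = 500, v = 500, t = 2012)  # peak: 2
surface_spec <- function(kind = c("constant", "linear_space", "gaussian_bump",
                                  "linear_time", "separable_product"),
                         base_value = 0, amplitude = 0,
                         center = c(500, 500), length_scale = 200,
                         time_slope = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(length_scale) || length(length_scale) != 1L ||
      length_scale <= 0)
    stop_gtwr("invalid_config", "length_scale must be a positive number")
  if (length(center) != 2L || any(!is.finite(center)))
    stop_gtwr("invalid_config", "center must be a finite (u, v) pair")
  structure(list(kind = kind, base_value = base_value, amplitude = amplitude,
                 center = as.numeric(center), length_scale = length_scale,
                 time_slope = time_slope),
            class = "surface_spec")
}

#' Evaluate a coefficient surface at space-time points
#'
#' Deterministic evaluation of a [surface_spec()] at coordinates `(u, v)`
#' and year `t`. Vectorised over `u`, `v`, `t`. Years outside the span used
#' to set `t0` extrapolate linearly (the temporal kinds are affine in `t`).
#'
#' @param spec a `surface_spec`.
#' @param u,v planar coordinates.
#' @param t year (real-valued).
#' @param t0 time origin; the first year of the panel. Defaults to
#'   `min(t)`.
#' @return numeric vector of coefficient values.
#' @export
evaluate_surface <- function(spec, u, v, t, t0 = min(t)) {
  stopifnot(inherits(spec, "surface_spec"))
  n <- max(length(u), length(v), length(t))
  u <- rep_len(as.numeric(u), n)
  v <- rep_len(as.numeric(v), n)
  t <- rep_len(as.numeric(t), n)
  bump <- function() {
    d2 <- (u - spec$center[1])^2 + (v - spec$center[2])^2
    exp(-d2 / (2 * spec$length_scale^2))
  }
  switch(spec$kind,
    constant = rep_len(spec$base_value, n),
    linear_space = spec$base_value + spec$amplitude *
      ((u - spec$center[1]) + (v - spec$center[2])) / spec$length_scale,
    gaussian_bump = spec$base_value + spec$amplitude * bump(),
    linear_time = spec$base_value + spec$time_slope * (t - t0),
    separable_product = (spec$base_value + spec$amplitude * bump()) *
      (1 + spec$time_slope * (t - t0))
  )
}

#' @export
#' @method print surface_spec
print.surface_spec <- function(x, ...) {
  cat("Coefficient surface:", x$kind, "\n")
  cat(sprintf("  base %.4g, amplitude %.4g, center (%g, %g), length scale %g, time slope %.4g\n",
              x$base_value, x$amplitude, x$center[1], x$center[2],
              x$length_scale, x$time_slope))
  invisible(x)
}
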