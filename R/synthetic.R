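# Synthetic city-panel generator.
#
# Emulates a balanced-to-mildly-unbalanced panel of Chinese prefecture-level
# cities observed annually: clustered planar coordinates in a bounded
# window, socioeconomic covariates on their published scales, and a birth
# rate generated from known space-time-varying coefficient surfaces plus
# Gaussian noise. Everything is a pure function of (config, seed).

#' Default covariate generating distributions
#'
#' Means and standard deviations of the nine socioeconomic covariates on
#' their analysis scales (log scales where the variable is conventionally
#' log-transformed): per-capita GDP (`pgdp`, ln of 10,000-yuan units),
#' urbanisation rate (`ur`), urban-rural income gap (`urig`), fiscal
#' science & technology expenditure share (`fste`, %), air quality index
#' (`aqi`, ln), house price (`hp`, ln yuan/m2), fiscal education
#' expenditure share (`fee`, %), public library books per 100 people
#' (`pbph`, ln), hospital beds per 1,000 people (`hbpt`, ln).
#'
#' Draws are independent Gaussians truncated at `mean +/- 4 sd` (truncation
#' that mild leaves the configured moments intact; it also means share
#' variables are not forced non-negative -- a documented simplification).
#'
#' @return data.frame with columns `variable`, `mean`, `sd`.
#' @export
default_covariates <- function() {
  data.frame(
    variable = c("pgdp", "ur", "urig", "fste", "aqi", "hp", "fee", "pbph",
                 "hbpt"),
    mean = c(1.5725, 0.5635, 2.3126, 1.7203, 3.6856, 8.5894, 17.5582,
             3.8781, 3.8223),
    sd = c(0.5620, 0.1466, 0.4491, 1.7666, 0.3862, 0.5105, 3.9247,
           0.7956, 0.3044),
    stringsAsFactors = FALSE
  )
}

default_surfaces <- function(vars) {
  # Plausible default truth: a spatially clustered baseline birth rate,
  # an economic-development effect that grows more negative over time, a
  # house-price effect with regional sign reversal, a small constant
  # education effect; all other coefficients zero.
  surfaces <- list(
    intercept = surface_spec("gaussian_bump", base_value = 8,
                             amplitude = 4, center = c(700, 300),
                             length_scale = 250)
  )
  for (v in vars) surfaces[[v]] <- surface_spec("constant", base_value = 0)
  if ("pgdp" %in% vars)
    surfaces$pgdp <- surface_spec("linear_time", base_value = -0.3,
                                  time_slope = -0.06)
  if ("hp" %in% vars)
    surfaces$hp <- surface_spec("gaussian_bump", base_value = 0.25,
                                amplitude = -0.5, center = c(300, 700),
                                length_scale = 300)
  if ("fee" %in% vars)
    surfaces$fee <- surface_spec("constant", base_value = 0.05)
  surfaces
}

#' Configure a synthetic city panel
#'
#' Bundles every knob of the generator into a validated config object.
#' Defaults emulate the study conditions of a 286-city, 2012--2021 panel:
#' clustered city coordinates in a 1,000 x 1,000 planar window, covariates
#' at their published means and standard deviations, and a missingness rate
#' chosen so the expected retained sample is about 2,648 records.
#'
#' @param n_cities number of cities (>= 1; >= 10 for any model fitting).
#' @param years strictly increasing integer vector of panel years.
#' @param layout `"uniform"` or `"clustered"` city placement.
#' @param n_clusters number of city agglomerations when
#'   `layout = "clustered"`.
#' @param covariates data.frame with columns `variable`, `mean`, `sd`
#'   giving the covariate generating distributions; see
#'   [default_covariates()].
#' @param coefficient_surfaces named list of [surface_spec()] objects; must
#'   contain `intercept` plus one entry per covariate. `NULL` uses a
#'   documented default truth.
#' @param noise_sd standard deviation of the Gaussian response noise, in
#'   the response's per-mille units.
#' @param missing_rate fraction of records dropped completely at random in
#'   `[0, 1)`, emulating exclusion of incomplete city-years.
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_cities = 286L,
                             years = 2012:2021,
                             layout = c("clustered", "uniform"),
                             n_clusters = 8L,
                             covariates = default_covariates(),
                             coefficient_surfaces = NULL,
                             noise_sd = 1.5,
                             missing_rate = 0.074,
                             seed = 1L) {
  layout <- match.arg(layout)
  n_cities <- as.integer(n_cities)
  years <- as.integer(years)
  if (n_cities < 1L)
    stop_gtwr("invalid_config", "n_cities must be >= 1")
  if (length(years) < 1L || any(diff(years) <= 0))
    stop_gtwr("invalid_config", "years must be strictly increasing")
  if (layout == "clustered" && n_clusters > n_cities)
    stop_gtwr("invalid_config",
              "n_clusters (%d) exceeds n_cities (%d)", n_clusters, n_cities)
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_gtwr("invalid_config", "noise_sd must be non-negative")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_gtwr("invalid_config", "missing_rate must be in [0, 1)")
  stopifnot(is.data.frame(covariates),
            all(c("variable", "mean", "sd") %in% names(covariates)))
  vars <- as.character(covariates$variable)
  if (is.null(coefficient_surfaces))
    coefficient_surfaces <- default_surfaces(vars)
  needed <- c("intercept", vars)
  missing_sf <- setdiff(needed, names(coefficient_surfaces))
  if (length(missing_sf))
    stop_gtwr("invalid_config",
              "missing coefficient surface(s): %s",
              paste(missing_sf, collapse = ", "))
  for (nm in needed)
    if (!inherits(coefficient_surfaces[[nm]], "surface_spec"))
      stop_gtwr("invalid_config", "surface '%s' is not a surface_spec", nm)
  structure(list(n_cities = n_cities, years = years, layout = layout,
                 n_clusters = as.integer(n_clusters),
                 covariates = covariates,
                 coefficient_surfaces = coefficient_surfaces[needed],
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Place cities in the planar window
#'
#' Draws `n_cities` point locations in the `[0, 1000] x [0, 1000]` planar
#' window (kilometre-like units). `"uniform"` scatters cities uniformly;
#' `"clustered"` first draws `n_clusters` agglomeration centres uniformly
#' in the central `[100, 900]^2` region, assigns cities to centres at
#' random, and scatters them with isotropic Gaussian spread (sd 60),
#' reflecting points that fall outside the window back inside.
#'
#' @param n_cities number of cities.
#' @param layout `"uniform"` or `"clustered"`.
#' @param n_clusters number of agglomerations (clustered layout).
#' @param seed integer seed.
#' @return data.frame with columns `city_id`, `u`, `v`.
#' @export
generate_city_layout <- function(n_cities, layout = c("uniform", "clustered"),
                                 n_clusters = 5L, seed = 1L) {
  layout <- match.arg(layout)
  n_cities <- as.integer(n_cities)
  if (n_cities < 1L) stop_gtwr("invalid_config", "n_cities must be >= 1")
  if (layout == "clustered" && n_clusters > n_cities)
    stop_gtwr("invalid_config",
              "n_clusters (%d) exceeds n_cities (%d)", n_clusters, n_cities)
  window <- c(0, 1000)
  with_seed(seed, {
    if (layout == "uniform") {
      u <- runif(n_cities, window[1], window[2])
      v <- runif(n_cities, window[1], window[2])
      cl <- rep(NA_integer_, n_cities)
    } else {
      cu <- runif(n_clusters, 100, 900)
      cv <- runif(n_clusters, 100, 900)
      cl <- sample.int(n_clusters, n_cities, replace = TRUE)
      # guarantee every cluster non-empty when possible
      if (n_cities >= n_clusters) cl[seq_len(n_clusters)] <- seq_len(n_clusters)
      u <- rnorm(n_cities, cu[cl], 60)
      v <- rnorm(n_cities, cv[cl], 60)
      reflect <- function(x) {
        x <- abs(x)                       # reflect at 0
        x <- window[2] - abs(window[2] - x)  # reflect at 1000
        pmin(pmax(x, window[1]), window[2])
      }
      u <- reflect(u)
      v <- reflect(v)
    }
    out <- data.frame(city_id = sprintf("c%03d", seq_len(n_cities)),
                      u = u, v = v, stringsAsFactors = FALSE)
    attr(out, "cluster") <- cl
    attr(out, "window") <- window
    out
  })
}

#' Simulate a city-year panel with known coefficient surfaces
#'
#' Generates the full panel: city layout, covariate draws, and a response
#' built from the configured coefficient surfaces,
#' `y_i = b0(u_i, v_i, t_i) + sum_k b_k(u_i, v_i, t_i) x_ik + e_i` with
#' `e_i ~ N(0, noise_sd^2)`. The true per-record coefficient values are
#' attached as the `"truth"` attribute (a data.frame keyed like the panel,
#' one column per surface) so fitted local coefficients can be scored
#' against them. Random streams for layout, covariates, noise, and
#' missingness are split deterministically, so e.g. changing `noise_sd`
#' never perturbs the coordinates.
#'
#' @param config a [synthetic_config()].
#' @return data.frame of class `panel_dataset` with columns `city_id`,
#'   `u`, `v`, `year`, `birth_rate`, and one column per covariate;
#'   attributes `truth` (true coefficients per record), `config`,
#'   `variable_names`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_cities = 30, years = 2012:2014, seed = 9)
#' panel <- simulate_panel(cfg)
#' head(attr(panel, "truth"))
simulate_panel <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  vars <- as.character(config$covariates$variable)
  layout <- generate_city_layout(config$n_cities, config$layout,
                                 config$n_clusters,
                                 seed = derive_seed(config$seed, "layout"))
  grid <- expand.grid(ci = seq_len(config$n_cities), year = config$years,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  panel <- data.frame(city_id = layout$city_id[grid$ci],
                      u = layout$u[grid$ci], v = layout$v[grid$ci],
                      year = grid$year, stringsAsFactors = FALSE)

  X <- with_seed(derive_seed(config$seed, "covariates"), {
    out <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
    for (j in seq_along(vars)) {
      m <- config$covariates$mean[j]
      s <- config$covariates$sd[j]
      x <- rnorm(n, m, s)
      out[, j] <- pmin(pmax(x, m - 4 * s), m + 4 * s)  # mild truncation
    }
    out
  })

  t0 <- min(config$years)
  truth <- matrix(NA_real_, n, length(vars) + 1L,
                  dimnames = list(NULL, c("intercept", vars)))
  for (nm in colnames(truth))
    truth[, nm] <- evaluate_surface(config$coefficient_surfaces[[nm]],
                                    panel$u, panel$v, panel$year, t0 = t0)
  eps <- with_seed(derive_seed(config$seed, "noise"),
                   rnorm(n, 0, config$noise_sd))
  panel$birth_rate <- truth[, "intercept"] +
    rowSums(truth[, vars, drop = FALSE] * X) + eps
  panel <- cbind(panel, as.data.frame(X))

  keep <- seq_len(n)
  if (config$missing_rate > 0) {
    keep <- with_seed(derive_seed(config$seed, "missing"),
                      which(runif(n) >= config$missing_rate))
  }
  panel <- panel[keep, , drop = FALSE]
  rownames(panel) <- NULL
  truth_df <- data.frame(city_id = panel$city_id, year = panel$year,
                         truth[keep, , drop = FALSE],
                         stringsAsFactors = FALSE, check.names = FALSE)
  structure(panel,
            truth = truth_df, config = config, variable_names = vars,
            dropped_count = n - length(keep),
            class = c("panel_dataset", "data.frame"))
}

#' Simulate a spatially clustered field over given cities
#'
#' A per-city scalar field built from Gaussian bumps: hot centres add
#' `amplitude * exp(-d^2 / (2 * length_scale^2))`, cold centres subtract
#' it, plus iid Gaussian noise. Serves as a controlled test bed for
#' hot/cold-spot detection.
#'
#' @param coords two-column matrix or data.frame of city coordinates.
#' @param hot_centers,cold_centers matrices (or length-2 vectors) of bump
#'   centres inside the coordinate window; may be `NULL`.
#' @param base baseline field level.
#' @param amplitude bump height; `0` gives a spatially unstructured field.
#' @param length_scale bump spatial scale.
#' @param noise_sd iid noise standard deviation.
#' @param seed integer seed.
#' @return numeric vector, one value per city.
#' @export
simulate_clustered_field <- function(coords, hot_centers = NULL,
                                     cold_centers = NULL, base = 10,
                                     amplitude = 3, length_scale = 150,
                                     noise_sd = 0.5, seed = 1L) {
  coords <- check_numeric_matrix_coords(coords)
  as_centers <- function(x) {
    if (is.null(x)) return(NULL)
    x <- if (is.null(dim(x))) matrix(x, ncol = 2, byrow = TRUE) else as.matrix(x)
    if (ncol(x) != 2) stop_gtwr("invalid_config", "centers must be (u, v) pairs")
    x
  }
  hot <- as_centers(hot_centers)
  cold <- as_centers(cold_centers)
  if (length_scale <= 0)
    stop_gtwr("invalid_config", "length_scale must be positive")
  bump_sum <- function(centers) {
    if (is.null(centers)) return(0)
    s <- 0
    for (r in seq_len(nrow(centers))) {
      d2 <- (coords[, 1] - centers[r, 1])^2 + (coords[, 2] - centers[r, 2])^2
      s <- s + exp(-d2 / (2 * length_scale^2))
    }
    s
  }
  field <- base + amplitude * bump_sum(hot) - amplitude * bump_sum(cold)
  field + with_seed(derive_seed(seed, "field"),
                    rnorm(nrow(coords), 0, noise_sd))
}

#' Write a panel (and its truth table) to CSV
#'
#' Long-format plain-text export: one row per city-year. When the panel
#' carries a `"truth"` attribute and `truth_path` is given, the true
#' coefficient table is written alongside.
#'
#' @param panel a `panel_dataset`.
#' @param path output CSV path.
#' @param truth_path optional CSV path for the true-coefficient table.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path, truth_path = NULL) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE)
  tr <- attr(panel, "truth")
  if (!is.null(truth_path) && !is.null(tr))
    utils::write.csv(tr, truth_path, row.names = FALSE)
  invisible(path)
}

#' @export
#' @method print synthetic_config
print.synthetic_config <- function(x, ...) {
  cat(sprintf("Synthetic panel config: %d cities x %d years (%d-%d), %s layout\n",
              x$n_cities, length(x$years), min(x$years), max(x$years),
              x$layout))
  cat(sprintf("  noise sd %.3g, missing rate %.3g, seed %d\n",
              x$noise_sd, x$missing_rate, x$seed))
  cat("  surfaces:",
      paste(sprintf("%s(%s)", names(x$coefficient_surfaces),
                    vapply(x$coefficient_surfaces, `[[`, "", "kind")),
            collapse = ", "), "\n")
  invisible(x)
}
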