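# Panel ingestion, variable transforms, per-year autocorrelation series,
# and the reporting surfaces (coefficient summary, phase comparison,
# temporal trend, coefficient maps), plus end-to-end orchestration.

#' Canonical covariate names
#' @return character vector of the nine covariate column names.
#' @export
covariate_names <- function() {
  c("pgdp", "ur", "urig", "fste", "aqi", "hp", "fee", "pbph", "hbpt")
}

#' Load a city-year panel
#'
#' Reads a long-format panel (CSV path or data.frame), validates the
#' schema, and drops (counting them) rows with missing required fields.
#' Duplicate `(city_id, year)` keys or non-numeric required columns are
#' errors.
#'
#' @param x CSV path or data.frame.
#' @param covariates required covariate column names.
#' @param response response column name.
#' @param coords coordinate column names.
#' @param time year column name.
#' @param id city identifier column name.
#' @return data.frame of class `panel_dataset`; attribute `dropped_count`
#'   holds the number of incomplete rows removed.
#' @export
load_panel <- function(x, covariates = covariate_names(),
                       response = "birth_rate", coords = c("u", "v"),
                       time = "year", id = "city_id") {
  df <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE)
        else as.data.frame(x)
  required <- c(id, coords, time, response, covariates)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop_gtwr("ingestion_error", "missing required column(s): %s",
              paste(miss, collapse = ", "))
  numeric_cols <- setdiff(required, id)
  for (cn in numeric_cols)
    if (!is.numeric(df[[cn]]))
      stop_gtwr("ingestion_error",
                "column '%s' is not numeric (first offending row: %d)",
                cn, which(is.na(suppressWarnings(
                  as.numeric(as.character(df[[cn]])))))[1])
  complete <- stats::complete.cases(df[required])
  dropped <- sum(!complete)
  if (dropped)
    message(sprintf("dropped %d record(s) with missing required fields",
                    dropped))
  df <- df[complete, , drop = FALSE]
  key <- paste(df[[id]], df[[time]], sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop_gtwr("ingestion_error", "duplicate (city_id, year) key(s): %s",
              paste(utils::head(gsub("\r", "/", dups), 5L),
                    collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df, variable_names = covariates, dropped_count = dropped,
            transform_log = character(),
            class = c("panel_dataset", "data.frame"))
}

#' Crude birth rate in per mille
#'
#' `1000 * births / average_population`.
#'
#' @param births annual births.
#' @param average_population average annual population (> 0).
#' @return birth rate(s) in per mille.
#' @export
compute_birth_rate <- function(births, average_population) {
  if (any(average_population <= 0))
    stop_gtwr("domain_error", "average_population must be positive")
  1000 * births / average_population
}

#' Apply the standard variable transforms
#'
#' Builds the analysis-scale covariates from raw ones: `pgdp` is the log
#' of GDP per capita expressed in `gdp_unit`-yuan units (default 10,000);
#' the columns in `log_cols` (air quality index, house price, library
#' books per 100 people, hospital beds per 1,000 people by default) are
#' log-transformed in place. Share/ratio variables (`ur`, `urig`, `fste`,
#' `fee`) pass through untouched. A non-positive value under a log raises
#' a `transform_error` naming the city-year.
#'
#' @param panel a panel data.frame with the raw columns.
#' @param gdp_col raw GDP per capita column (yuan); omitted if absent.
#' @param gdp_unit yuan per GDP unit for the log transform.
#' @param log_cols columns to log-transform in place.
#' @return the panel with transformed columns and an updated
#'   `transform_log` attribute.
#' @export
apply_transforms <- function(panel, gdp_col = "gdp_per_capita",
                             gdp_unit = 1e4,
                             log_cols = c("aqi", "hp", "pbph", "hbpt")) {
  log_of <- function(vals, label) {
    bad <- which(vals <= 0)
    if (length(bad)) {
      where <- if (all(c("city_id", "year") %in% names(panel)))
        sprintf(" (first at %s/%s)", panel$city_id[bad[1]],
                panel$year[bad[1]])
      else sprintf(" (first at row %d)", bad[1])
      stop_gtwr("transform_error",
                "non-positive value under log transform of %s%s",
                label, where)
    }
    log(vals)
  }
  applied <- character()
  if (gdp_col %in% names(panel)) {
    panel$pgdp <- log_of(panel[[gdp_col]] / gdp_unit,
                         sprintf("%s/%g", gdp_col, gdp_unit))
    applied <- c(applied, sprintf("pgdp = ln(%s / %g)", gdp_col, gdp_unit))
  }
  for (cn in intersect(log_cols, names(panel))) {
    panel[[cn]] <- log_of(panel[[cn]], cn)
    applied <- c(applied, sprintf("%s = ln(%s)", cn, cn))
  }
  attr(panel, "transform_log") <- c(attr(panel, "transform_log"), applied)
  panel
}

#' Annual Moran's I series
#'
#' Moran's I on each year's cross-section of the response. Years with
#' fewer than 3 cities are skipped with a warning.
#'
#' @inheritParams morans_i_by_period
#' @return data.frame of class `moran_series` with columns `year`, `n`,
#'   `moran_i`, `expected`, `z_score`, `p_analytic`, `p_permutation`;
#'   attribute `results` holds the full per-year [morans_i()] objects.
#' @export
annual_moran_series <- function(panel, response = "birth_rate",
                                coords = c("u", "v"), time = "year",
                                weights_args = list(),
                                n_permutations = 999L, seed = 1L) {
  years <- sort(unique(panel[[time]]))
  results <- list()
  rows <- list()
  for (k in seq_along(years)) {
    yr <- years[k]
    sub <- panel[panel[[time]] == yr, , drop = FALSE]
    if (nrow(sub) < 3L) {
      warn_gtwr("sparse_year", "year %s has %d cities; skipped",
                yr, nrow(sub))
      next
    }
    w <- do.call(build_weights, c(list(coords = sub[, coords]),
                                  weights_args))
    m <- morans_i(sub[[response]], w, n_permutations = n_permutations,
                  seed = seed + k)
    results[[as.character(yr)]] <- m
    rows[[length(rows) + 1L]] <- data.frame(
      year = yr, n = m$n, moran_i = m$statistic,
      expected = m$expected_value, z_score = m$z_score,
      p_analytic = m$p_analytic, p_permutation = m$p_permutation)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  class(out) <- c("moran_series", "data.frame")
  out
}

coef_table <- function(fit) {
  if (inherits(fit, "gtwr")) {
    df <- as.data.frame(fit)
    vars <- c("intercept",
              setdiff(fit$variable_names, "(Intercept)"))
    list(df = df, vars = vars)
  } else if (is.data.frame(fit)) {
    if (!"year" %in% names(fit))
      stop_gtwr("invalid_config",
                "a coefficient table needs a 'year' column")
    drop <- c("city_id", "u", "v", "year", "fitted", "residual")
    vars <- setdiff(names(fit)[vapply(fit, is.numeric, TRUE)], drop)
    list(df = fit, vars = vars)
  } else {
    stop_gtwr("invalid_config",
              "fit must be a gtwr object or a coefficient data.frame")
  }
}

#' Table of local-coefficient order statistics
#'
#' The coefficient-distribution report: mean, minimum, lower quartile,
#' median, upper quartile and maximum of the local coefficients of every
#' model term, over all observations. Identical content to
#' [summary.gtwr()], but also accepts the exported fit table (so every
#' report is recomputable from the fit CSV alone).
#'
#' @param fit a [gtwr()] fit or its [as.data.frame.gtwr()] table.
#' @return data.frame with columns `variable`, `avg`, `min`, `lq`, `med`,
#'   `uq`, `max`.
#' @export
summarize_coefficients <- function(fit) {
  ct <- coef_table(fit)
  qs <- t(vapply(ct$vars, function(vn)
    stats::quantile(ct$df[[vn]], c(0, 0.25, 0.5, 0.75, 1), type = 7,
                    names = FALSE), numeric(5)))
  out <- data.frame(variable = ct$vars,
                    avg = vapply(ct$vars, function(vn) mean(ct$df[[vn]]), 0.0),
                    min = qs[, 1], lq = qs[, 2], med = qs[, 3],
                    uq = qs[, 4], max = qs[, 5],
                    stringsAsFactors = FALSE, row.names = NULL)
  if (inherits(fit, "gtwr")) attr(out, "adj_r2") <- fit$adj_r2
  out
}

#' Phase-wise average coefficients and their change
#'
#' Mean local coefficient per model term over the observations falling in
#' each of two disjoint year phases, and the change `phase_b - phase_a`
#' (computed at full precision before any display rounding). With
#' `weighting = "year"` the phase mean averages the annual means instead
#' of the raw observations (the two agree on a balanced panel).
#'
#' @param fit a [gtwr()] fit or its exported coefficient table.
#' @param phase_a,phase_b disjoint integer year sets.
#' @param names_ab labels for the two phases.
#' @param weighting `"observation"` (default) or `"year"`.
#' @return data.frame of class `phase_comparison` with columns `variable`,
#'   the two phase means, and `change`.
#' @export
#' @examples
#' cfg <- synthetic_config(n_cities = 25, years = 2012:2015, seed = 2,
#'                         missing_rate = 0)
#' fit <- gtwr(birth_rate ~ pgdp + hp, simulate_panel(cfg),
#'             bandwidth = 400, tau = 0)
#' phase_comparison(fit, 2012:2013, 2014:2015)
phase_comparison <- function(fit, phase_a = 2012:2016,
                             phase_b = 2017:2021,
                             names_ab = c("phase_a", "phase_b"),
                             weighting = c("observation", "year")) {
  weighting <- match.arg(weighting)
  phase_a <- as.integer(phase_a); phase_b <- as.integer(phase_b)
  if (length(intersect(phase_a, phase_b)))
    stop_gtwr("invalid_config", "phases must be disjoint")
  ct <- coef_table(fit)
  phase_mean <- function(years) {
    sel <- ct$df$year %in% years
    if (!any(sel)) stop_gtwr("invalid_config", "a phase selects no records")
    if (weighting == "observation") {
      vapply(ct$vars, function(vn) mean(ct$df[[vn]][sel]), 0.0)
    } else {
      vapply(ct$vars, function(vn) {
        ann <- tapply(ct$df[[vn]][sel], ct$df$year[sel], mean)
        mean(ann)
      }, 0.0)
    }
  }
  ma <- phase_mean(phase_a)
  mb <- phase_mean(phase_b)
  out <- data.frame(variable = ct$vars, a = unname(ma), b = unname(mb),
                    change = unname(mb - ma), stringsAsFactors = FALSE)
  names(out)[2:3] <- names_ab
  attr(out, "phases") <- list(phase_a, phase_b)
  class(out) <- c("phase_comparison", "data.frame")
  out
}

#' Per-year mean local coefficients
#'
#' The annual trend of each model term's average local coefficient, in
#' long (tidy) format ready for plotting or CSV export.
#'
#' @param fit a [gtwr()] fit or its exported coefficient table.
#' @return data.frame with columns `year`, `variable`,
#'   `mean_coefficient`.
#' @export
temporal_trend <- function(fit) {
  ct <- coef_table(fit)
  years <- sort(unique(ct$df$year))
  out <- expand.grid(year = years, variable = ct$vars,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$mean_coefficient <- mapply(function(yr, vn)
    mean(ct$df[[vn]][ct$df$year == yr]), out$year, out$variable)
  out
}

#' Per-city average coefficient of one variable
#'
#' Averages a variable's local coefficients over the selected years at
#' each city, the data behind a coefficient choropleth. When `geometries`
#' (a GeoJSON FeatureCollection, as a list or file path, with a `city_id`
#' feature property) is supplied, the value is attached as a property and
#' the enriched FeatureCollection returned in attribute `geojson`.
#'
#' @param fit a [gtwr()] fit or its exported coefficient table.
#' @param variable model term to map.
#' @param years year subset (`NULL` = all).
#' @param geometries optional GeoJSON FeatureCollection list or path.
#' @return data.frame with `city_id`, `u`, `v`, `value`.
#' @export
coefficient_map <- function(fit, variable, years = NULL,
                            geometries = NULL) {
  ct <- coef_table(fit)
  if (!variable %in% ct$vars)
    stop_gtwr("invalid_config", "unknown variable '%s'; available: %s",
              variable, paste(ct$vars, collapse = ", "))
  df <- ct$df
  if (!is.null(years)) df <- df[df$year %in% years, , drop = FALSE]
  if (!nrow(df)) stop_gtwr("invalid_config", "year selection is empty")
  agg <- stats::aggregate(df[, c("u", "v", variable)],
                          by = list(city_id = df$city_id), FUN = mean)
  names(agg)[names(agg) == variable] <- "value"
  if (!is.null(geometries)) {
    gj <- if (is.character(geometries))
      jsonlite::fromJSON(geometries, simplifyVector = FALSE) else geometries
    val <- stats::setNames(agg$value, agg$city_id)
    gj$features <- lapply(gj$features, function(f) {
      cid <- f$properties$city_id
      f$properties[[paste0("coef_", variable)]] <-
        if (!is.null(cid) && cid %in% names(val)) unname(val[[cid]]) else NA
      f
    })
    attr(agg, "geojson") <- gj
  }
  agg
}

#' Write a per-city value table as GeoJSON points
#'
#' @param df data.frame with `city_id`, `u`, `v` and value columns.
#' @param path output path.
#' @return `path` invisibly.
#' @export
export_geojson <- function(df, path) {
  feat <- lapply(seq_len(nrow(df)), function(i) {
    props <- as.list(df[i, setdiff(names(df), c("u", "v")), drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$u[i], df$v[i])),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = feat)
  writeLines(jsonlite::toJSON(fc, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Run the full spatiotemporal analysis
#'
#' End-to-end orchestration: load (or simulate) the panel, apply
#' transforms if raw columns are present, compute the annual Moran series
#' and the pre/post-phase Moran comparison, label hot/cold spots (Gi*)
#' and LISA clusters for selected years, fit the OLS baseline, calibrate
#' and fit the GTWR model, run the non-stationarity test, and write every
#' report table plus a manifest recording all settings. Re-running with
#' the same config and seed reproduces all outputs bit-identically.
#'
#' @param config a list (or path to a JSON file) with elements:
#'   `panel` (CSV path) or `synthetic` (arguments to [synthetic_config()]);
#'   optional `response`, `covariates`, `weights` (args to
#'   [build_weights()]), `phases` (list of two year vectors),
#'   `hotspot_years`, `kernel` (list: `family`, `bandwidth`, `tau`,
#'   `tau_grid`), `n_permutations`, `alpha`, `seed`, `out_dir`.
#' @param verbose log per-stage progress and timings to stderr?
#' @return (invisibly) a list with the panel, fits, tables and file paths.
#' @export
run_full_analysis <- function(config, verbose = TRUE) {
  if (is.character(config)) config <- jsonlite::fromJSON(config,
                                                         simplifyVector = TRUE)
  say <- function(stage, t0) if (verbose)
    message(sprintf("[%s] done in %.2fs", stage,
                    as.numeric(proc.time()[3]) - t0))
  stage <- function(name, expr) {
    t0 <- as.numeric(proc.time()[3])
    r <- tryCatch(expr, error = function(e)
      stop_gtwr("pipeline_error", "stage '%s' failed: %s", name,
                conditionMessage(e)))
    say(name, t0)
    r
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) tempfile("gtwr_run_") else
    config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  response <- config$response %||% "birth_rate"
  covariates <- config$covariates %||% covariate_names()
  weights_args <- config$weights %||% list()
  nperm <- config$n_permutations %||% 999L
  alpha <- config$alpha %||% 0.05
  paths <- list()

  panel <- stage("panel", {
    if (!is.null(config$panel)) {
      load_panel(config$panel, covariates = covariates,
                 response = response)
    } else {
      sc_args <- config$synthetic %||% list()
      sc_args$seed <- sc_args$seed %||% seed
      p <- simulate_panel(do.call(synthetic_config, sc_args))
      covariates <- intersect(covariates, names(p))
      paths$panel <- file.path(out_dir, "panel.csv")
      write_panel(p, paths$panel,
                  truth_path = file.path(out_dir, "panel_truth.csv"))
      p
    }
  })
  if (any(c("gdp_per_capita") %in% names(panel)))
    panel <- stage("transforms", apply_transforms(panel))

  annual <- stage("annual_moran",
    annual_moran_series(panel, response = response,
                        weights_args = weights_args,
                        n_permutations = nperm, seed = seed))
  paths$annual_moran <- file.path(out_dir, "annual_moran.csv")
  utils::write.csv(round6(annual), paths$annual_moran, row.names = FALSE)

  phases <- config$phases %||% list(2012:2016, 2017:2021)
  phases <- lapply(phases, as.integer)
  have_phases <- all(vapply(phases, function(ph)
    any(panel$year %in% ph), TRUE))
  prepost <- NULL
  if (have_phases) {
    prepost <- stage("prepost_moran",
      morans_i_by_period(panel, phases[[1]], phases[[2]],
                         response = response, weights_args = weights_args,
                         n_permutations = nperm, seed = seed))
    paths$prepost_moran <- file.path(out_dir, "prepost_moran.json")
    jsonlite::write_json(list(I_a = prepost$I_a, I_b = prepost$I_b,
                              percent_change = prepost$percent_change),
                         paths$prepost_moran, auto_unbox = TRUE, digits = NA)
  }

  yr_range <- range(panel$year)
  hotspot_years <- config$hotspot_years %||%
    unique(c(yr_range[1], intersect(2017, panel$year), yr_range[2]))
  stage("hotspots", for (yr in hotspot_years) {
    sub <- panel[panel$year == yr, , drop = FALSE]
    w_gi <- do.call(build_weights,
                    utils::modifyList(list(coords = sub[, c("u", "v")],
                                           scheme = "distance_band",
                                           row_standardize = FALSE,
                                           include_self = TRUE),
                                      weights_args[setdiff(names(weights_args),
                                                           c("scheme", "include_self",
                                                             "row_standardize"))]))
    gi <- getis_ord_gi_star(sub[[response]], w_gi)
    gi$id <- sub$city_id
    utils::write.csv(round6(gi), file.path(out_dir,
                                           sprintf("gistar_%s.csv", yr)),
                     row.names = FALSE)
    w_li <- do.call(build_weights, c(list(coords = sub[, c("u", "v")]),
                                     weights_args))
    li <- local_moran(sub[[response]], w_li, n_permutations = nperm,
                      alpha = alpha, seed = seed + yr %% 1000L)
    li$id <- sub$city_id
    utils::write.csv(round6(li), file.path(out_dir,
                                           sprintf("lisa_%s.csv", yr)),
                     row.names = FALSE)
  })

  fml <- stats::as.formula(paste(response, "~",
                                 paste(covariates, collapse = " + ")))
  ols <- stage("ols", fit_ols(fml, panel))
  paths$ols <- file.path(out_dir, "ols.json")
  jsonlite::write_json(list(coefficients = as.list(ols$coefficients),
                            se = as.list(ols$se), adj_r2 = ols$adj_r2),
                       paths$ols, auto_unbox = TRUE, digits = NA)

  kcfg <- config$kernel %||% list()
  fit <- stage("gtwr", gtwr(fml, panel,
                            bandwidth = kcfg$bandwidth,
                            tau = kcfg$tau,
                            kernel = kcfg$family %||% "gaussian",
                            tau_grid = kcfg$tau_grid,
                            verbose = verbose))
  paths$fit <- file.path(out_dir, "gtwr_fit.csv")
  utils::write.csv(as.data.frame(fit), paths$fit, row.names = FALSE)
  paths$diagnostics <- file.path(out_dir, "diagnostics.json")
  jsonlite::write_json(list(bandwidth = fit$kernel$bandwidth,
                            tau = fit$tau, family = fit$kernel$family,
                            hat_trace = fit$hat_trace,
                            adj_r2 = fit$adj_r2, aicc = fit$aicc,
                            cv_score = fit$cv_score,
                            ols_adj_r2 = ols$adj_r2),
                       paths$diagnostics, auto_unbox = TRUE, digits = NA)

  nst <- stage("nonstationarity", nonstationarity_test(fit, ols))
  paths$nonstationarity <- file.path(out_dir, "nonstationarity.csv")
  utils::write.csv(round6(nst), paths$nonstationarity, row.names = FALSE)

  summ <- stage("report", summarize_coefficients(fit))
  paths$coef_summary <- file.path(out_dir, "coef_summary.csv")
  utils::write.csv(round6(summ), paths$coef_summary, row.names = FALSE)
  trend <- temporal_trend(fit)
  paths$trend <- file.path(out_dir, "temporal_trend.csv")
  utils::write.csv(round6(trend), paths$trend, row.names = FALSE)
  phase_cmp <- NULL
  if (have_phases) {
    phase_cmp <- phase_comparison(fit, phases[[1]], phases[[2]])
    paths$phase_comparison <- file.path(out_dir, "phase_comparison.csv")
    utils::write.csv(round6(phase_cmp), paths$phase_comparison,
                     row.names = FALSE)
  }

  manifest <- list(seed = seed, response = response,
                   covariates = covariates,
                   weights = weights_args, phases = phases,
                   hotspot_years = hotspot_years,
                   n_permutations = nperm, alpha = alpha,
                   kernel = list(family = fit$kernel$family,
                                 bandwidth = fit$kernel$bandwidth,
                                 tau = fit$tau),
                   synthetic = config$synthetic,
                   panel = config$panel, out_dir = out_dir)
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(panel = panel, annual_moran = annual, prepost = prepost,
                 ols = ols, fit = fit, nonstationarity = nst,
                 coef_summary = summ, temporal_trend = trend,
                 phase_comparison = phase_cmp, paths = paths,
                 out_dir = out_dir, manifest = manifest))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# report CSVs carry 6 decimals; fit exports keep full precision
round6 <- function(df) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, 6L)
  df
}
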