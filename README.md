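# gtwr

Spatiotemporal analysis of city-level demographic panels: geographically
and temporally weighted regression (GTWR) with cross-validated bandwidth
calibration, spatial autocorrelation and hot/cold-spot statistics, and a
synthetic panel generator with known coefficient surfaces.

## Who this is for

Demographers and spatial epidemiologists working with city-year panels —
for example, the crude birth rate (births per 1,000 population, ‰) of a
few hundred cities observed over a decade, together with socioeconomic
covariates (log GDP per capita, urbanisation rate, urban–rural income gap,
expenditure shares, log air quality index, log house price, log hospital
beds and library books per capita). A global regression on such a panel
reports one coefficient per covariate and hides how associations differ
between regions and policy phases. This package estimates them locally.

## The model

GTWR gives each observation its own coefficient vector,

    y_i = β0(u_i, v_i, t_i) + Σ_k βk(u_i, v_i, t_i) x_ik + ε_i,

estimated at every fit point by weighted least squares,
`β̂(i) = (XᵀW_iX)⁻¹ XᵀW_i y`, with kernel weights decaying in the combined
space-time distance `d²_ij = (u_i−u_j)² + (v_i−v_j)² + τ (t_i−t_j)²`. The
bandwidth `h` and the space-time ratio `τ` are calibrated by leave-one-out
cross-validation (golden-section search on `log h` over a `τ` grid).
`τ = 0` is a purely spatial GWR; as `h → ∞` every local fit collapses to
OLS. Diagnostics follow the GWR conventions (hat-trace effective
parameters, adjusted R², AICc).

Alongside the model: global Moran's I (analytic and permutation
inference), local Moran / LISA cluster labels (HH/LL/HL/LH), Getis-Ord
Gi\* hot/cold-spot categories, k-nearest-neighbour / distance-band /
inverse-distance spatial weights, and reporting tables (coefficient order
statistics, phase-mean comparisons, annual coefficient trends, per-city
coefficient maps with GeoJSON export). See the methods vignette
(`vignettes/gtwr-methods.Rmd`) for formulas, conventions and design
choices.

## Worked example

The package ships a generator whose defaults emulate a 286-city,
2012–2021 panel; here a smaller one keeps the example quick.

```r
library(gtwr)

cfg   <- synthetic_config(n_cities = 100, years = 2012:2021, seed = 42)
panel <- simulate_panel(cfg)           # 930 rows after random exclusions

## is the birth rate spatially clustered in the last year?
w <- build_weights(panel[panel$year == 2021, c("u", "v")])
morans_i(panel$birth_rate[panel$year == 2021], w, seed = 1)
#> Moran's I = 0.4639 (n = 90)
#>   E[I] = -0.0112, z = 9.306, analytic p = 1.327e-20, permutation p = 0.001 (999 perms)

## fit GTWR with CV-calibrated bandwidth
fit <- gtwr(birth_rate ~ pgdp + ur + urig + fste + aqi + hp + fee +
              pbph + hbpt, panel)
fit
#> n = 930 observations, 10 local coefficients each
#> gaussian kernel, fixed bandwidth h = 131.966, tau = mu/lambda = 0
#> Effective parameters tr(S) = 92.95
#> Adjusted R-squared: 0.5860   AICc: 3548.21   CV score: 2427.89

summary(fit)       # per-variable AVG / MIN / LQ / MED / UQ / MAX
#>     variable        avg        min         lq         med         uq       max
#>  (Intercept)  8.0399300 -3.4970000  6.0841400  8.12130000 10.2698000 12.779300
#>         pgdp -0.5824190 -1.0424300 -0.7187550 -0.56314700 -0.4313630  0.170300
#>  ...

ols <- fit_ols(birth_rate ~ pgdp + ur + urig + fste + aqi + hp + fee +
                 pbph + hbpt, panel)
ols$adj_r2                             # 0.025 -- the global fit explains
                                       # little of a locally varying truth
nonstationarity_test(fit, ols)         # IQR of local betas vs 2 x OLS SE
#>  variable   iqr_gtwr two_se_ols nonstationary
#>      pgdp 0.28739222 0.27820324          TRUE
#>       ur  0.81535296 1.07939641         FALSE
#>  ...

## phase-wise mean coefficients and their change
phase_comparison(fit, 2012:2016, 2017:2021,
                 names_ab = c("fluctuation", "downward"))
```

Reading the output: the generator's default truth makes the local GDP
effect negative and drifting downwards (mean local `pgdp` coefficient
−0.58 per log-unit of GDP, on the ‰ birth-rate scale), leaves most other
coefficients near zero, and puts strong spatial structure in the baseline
— which is why GTWR's adjusted R² (0.59) dwarfs OLS's (0.03) and why the
non-stationarity screen flags the spatially varying terms. Because the
panel is synthetic, every fitted surface can be scored against the truth
stored in `attr(panel, "truth")`.

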