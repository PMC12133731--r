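---
title: "Methods: spatiotemporally weighted regression and cluster statistics for city panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporally weighted regression and cluster statistics for city panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtwr)
```

## The problem

City-level demographic indicators such as the crude birth rate (births per
1,000 population per year, in per mille) are shaped by socioeconomic
conditions — income, urbanisation, housing costs, air quality, education and
health investment — whose influence is neither constant over a country's
territory nor stable over a decade of policy change. A single global
regression only reports the average association and hides exactly the
heterogeneity of interest. This package implements the two ingredients of a
spatiotemporal analysis of such panels:

1. **Cluster statistics** — global and local Moran's I and the Getis-Ord
   Gi\* statistic — that quantify whether and where the outcome clusters in
   space, per year and between policy phases.
2. **Geographically and temporally weighted regression (GTWR)** — a local
   linear model that gives every city-year observation its own coefficient
   vector, so the association between each covariate and the outcome can be
   mapped over space and traced over time.

## The GTWR model

The model is

$$ y_i = \beta_0(u_i, v_i, t_i) + \sum_k \beta_k(u_i, v_i, t_i)\, x_{ik} + \varepsilon_i, $$

where $(u_i, v_i)$ are projected planar coordinates, $t_i$ the observation
year, and each coefficient is an unknown smooth function of space-time
location. Estimation is pointwise weighted least squares: at fit point $i$,

$$ \hat\beta(i) = (X^\top W_i X)^{-1} X^\top W_i y, $$

with $W_i$ diagonal and $w_{ij}$ a kernel in the combined squared
space-time distance

$$ d_{ij}^2 = \lambda\left[(u_i-u_j)^2 + (v_i-v_j)^2\right] + \mu (t_i-t_j)^2 . $$

Only the ratio $\tau = \mu/\lambda$ is identifiable jointly with the kernel
bandwidth $h$, so the implementation fixes $\lambda = 1$ and calibrates
$(\tau, h)$. The default kernel is Gaussian, $w = \exp(-d^2/h^2)$: its
strictly positive weights mean no observation can become isolated, which
keeps leave-one-out cross-validation total. A bisquare kernel
($w = (1-d^2/h^2)^2$ inside $h$, zero outside) is available for users who
want compact support; with it, a bandwidth too small to reach $k+1$
neighbours makes the CV score infinite rather than silently dropping the
point.

### Calibration

`gtwr_bandwidth()` minimises the leave-one-out CV score
$\sum_i (y_i - \hat y_{(i)})^2$, where $\hat y_{(i)}$ refits at point $i$
with its self-weight forced to zero. For each candidate $\tau$, $h$ is
optimised by golden-section search on $\log h$, bracketed between the
smallest non-zero and twice the largest pairwise combined distance; the
$(\tau, h)$ pair with the global minimum wins. The search contains no
randomness, so repeated calibrations are identical.

The candidate grid for $\tau$ needs care. A raw grid such as
$\{0, 0.25, 0.5, 1, 2, 4, 8\}$ is only meaningful if spatial and temporal
separations are numerically comparable; with coordinates in kilometre-like
units (extent $\sim 10^3$) and time in years (extent $\sim 10$), temporal
distance would never compete with spatial distance at any $\tau \le 8$, and
the calibration would be unable to express temporal locality at all. The
default grid therefore scales the raw grid by the squared ratio of spatial
to temporal extent, making it unit-free: $\tau$ candidates span "time does
not matter" ($\tau = 0$) through "a year of separation counts like the full
map diagonal divided by the year range, and beyond". Users can always pass
an explicit `tau_grid`. Time is centred internally so $\mu\,\Delta t^2$
stays well scaled; a `causal = TRUE` option restricts local fits to
past-or-present observations (off by default, since the standard GTWR
formulation weights both directions in time symmetrically).

### Diagnostics

Each local solve contributes one row of the hat matrix $S$; its trace is
the model's effective number of parameters, computed exactly as
$s_{ii} = w_{ii}\, x_i^\top (X^\top W_i X)^{-1} x_i$. The fit reports

* adjusted $R^2 = 1 - \dfrac{RSS/(n - \mathrm{tr}\,S)}{TSS/(n-1)}$,
* $AICc = 2n\log\hat\sigma + n\log 2\pi + n\,\dfrac{n + \mathrm{tr}\,S}{n - 2 - \mathrm{tr}\,S}$
  with $\hat\sigma^2 = RSS/n$ (the GWR convention), and
* the CV score of the fitted specification.

Numerical choices: the local normal equations are solved by Cholesky
factorisation; a near-singular weighted design receives a ridge of
$10^{-8}$ times the mean diagonal of $X^\top W X$ before a hard
`singular_fit` error is considered. As $h \to \infty$ every local fit
collapses to global OLS (verified to $10^{-6}$ in the tests), and $\tau = 0$
is exactly a purely spatial GWR — the fit is then provably invariant to the
time column.

### Non-stationarity screen

Following the usual comparison for locally varying coefficient models, a
covariate is flagged non-stationary when the interquartile range of its $n$
local estimates strictly exceeds twice its OLS standard error. Quartiles
use linear interpolation (`stats::quantile` type 7); the flag depends on
this convention, which is why it is pinned and tested. The intercept is
excluded by default: the screen targets the substantive covariates, and
local intercept estimates absorb residual spatial level shifts that the
comparison would over-flag (`include_intercept = TRUE` restores it). The
screen is anticonservative by construction — local estimates carry their own
sampling noise, which inflates the IQR — so it is a screen, not a formal
test.

## Spatial cluster statistics

**Weights.** `build_weights()` supports k-nearest-neighbour (ties broken by
unit order), distance-band, and inverse-distance-within-band schemes. The
default band is the smallest distance leaving no unit isolated (the
minimum-spanning-distance rule): real city systems have remote members, and
a fixed band chosen by eye routinely strands them. Isolates that survive a
user-supplied band raise a named warning and are excluded from statistics
rather than erroring. Moran/LISA default to row-standardised
inverse-distance weights; Gi\* uses a binary band including self, as that
statistic requires $w_{ii} > 0$.

**Global Moran's I** is $(n/S_0)\,\sum_{ij} w_{ij} z_i z_j / \sum_i z_i^2$
with expectation $-1/(n-1)$; the analytic z-score uses the
normality-assumption variance, and the permutation p-value relabels values
over units with the $+1$-corrected pseudo-p,
$p = (1 + \#\{\text{as-or-more extreme}\})/(1 + B)$, extremeness measured
two-sided about the expectation. $B = 999$ by default.

**Local Moran (LISA)** is $I_i = z_i \sum_j w_{ij} z_j$ with deviates
standardised by the population standard deviation (so
$\sum_i I_i = S_0 \cdot I$, which the tests exploit). Inference is by
conditional permutation — unit $i$ held fixed, neighbour values drawn
without replacement from the rest — and quadrant labels HH/LL/HL/LH are
assigned only below the significance level (raw pseudo-p at
$\alpha = 0.05$ by default; a Benjamini-Hochberg option exists because
multiple-testing practice varies in applied work).

**Getis-Ord Gi\*** uses the textbook z-score form with the global mean and
population standard deviation; categories apply two-sided normal quantiles
at 90/95/99% confidence. A unit whose (self-inclusive) neighbourhood spans
all units with uniform weight has a vanishing denominator and carries no
local information; it is assigned $z = 0$. A constant field has zero
variance and is a degenerate-input error for all three statistics.

**Phase comparison.** `morans_i_by_period()` compares autocorrelation
before and after a policy break. The published account of this comparison
does not state whether period values are pooled city means or year-stacked
observations; the default aggregates each city to its period mean (one
value per city, same units across periods), with `aggregate = "year_mean"`
(average of annual Moran's I) exposed as the alternative. The percent
change is $100\,(I_b - I_a)/I_a$ and is reported as undefined when
$I_a = 0$.

## The synthetic panel generator

Because the underlying yearbook panel is not redistributable, the
generator is the package's test bed: it emulates a balanced-to-mildly
unbalanced panel of 286 cities over 2012–2021 and, crucially, records the
true coefficient surfaces so fits can be scored for parameter recovery.

* **Window and layout.** Cities live in a $[0, 1000]^2$ planar window
  (kilometre-like units; distances are metric). The clustered layout draws
  agglomeration centres uniformly in the central region and scatters
  cities around them with Gaussian spread (sd 60), reflecting overshoots
  back into the window — a stylised stand-in for city agglomerations, not
  any real geography.
* **Covariates.** Independent Gaussians at the published means and
  standard deviations of the nine covariates on their analysis scales,
  truncated at $\pm 4$ sd. The mild truncation leaves the configured
  moments intact (the tests check sample means against 3 standard errors
  at $n = 2{,}860$); it also means share variables are not forced
  non-negative — a documented unrealism that matters to none of the
  downstream computations. Real covariates are spatially autocorrelated
  and cross-correlated; the generator deliberately omits both, so passing
  recovery tests demonstrate correctness of the estimator, not robustness
  to collinearity.
* **Response.** $y = \beta_0(u,v,t) + \sum_k \beta_k(u,v,t)x_k +
  \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$ with $\sigma = 1.5$‰ by
  default. Default surfaces encode a plausible truth — a spatially clustered
  baseline, an economic-development effect that grows more negative over
  time, a house-price effect with a regional sign reversal, a small
  constant education effect — on the per-mille scale of the response.
  Surface kinds: constant, planar ramp, Gaussian bump
  ($\beta = b + a\,e^{-d^2/2\ell^2}$), linear drift in time, and a
  separable product defined as the bump spatial factor times
  $(1 + \text{slope}\,(t - t_0))$ (the factorisation is this package's
  choice; any multiplicative pairing would do).
* **Missingness** is completely at random at rate 0.074 by default, so the
  expected retained sample ($2860 \times 0.926 \approx 2648$) matches the
  published panel's size after exclusions. Simulated birth rates are not
  clamped at zero: clamping would bias recovery scoring, and negative
  draws are vanishingly rare at the default noise level.
* **Determinism.** Every generator is a pure function of (config, seed),
  and the random streams for layout, covariates, noise and missingness are
  split deterministically — adding a covariate never perturbs the
  coordinates.

## Problem sizes and what the tests show

The test-bed sizes are chosen to make each property checkable in seconds
to minutes while remaining in the regime where the methods operate:
oracle comparisons on grids of $\le 25$ points and weighted systems of
$n \le 8$ (against literal double-loop formula evaluation and explicit
normal-equation inversion); reduction-chain checks on a 100-observation
panel; parameter recovery on a 200-city $\times$ 5-year panel with a
bump of amplitude 2 and scale 200 on one coefficient, linear drift on a
second, and noise sd 0.5; hot/cold-spot detection on 120 cities with two
planted blobs; and permutation-test calibration over 500 replicates of an
unstructured field at $n = 50$, which must not reject above 7% at nominal
5%. Recovery on these panels shows the estimator tracks smooth coefficient
surfaces far better than the OLS constant (RMSE ratios around 0.3); it
does not show performance under covariate collinearity, irregular
observation density, or measurement error, none of which the generator
emulates.

## Limitations

* Fixed bandwidth is the default; the adaptive (neighbour-count) variant
  is implemented but secondary, and no per-variable (multiscale)
  bandwidths are offered.
* No mixed/semiparametric GTWR and no bootstrap inference on local
  coefficients.
* Coordinates must be projected planar; longitude/latitude should be
  projected (e.g. an equal-area projection) before fitting — the package
  does not reproject.
* The non-stationarity screen inherits the anticonservatism discussed
  above.
* Reports are descriptive: the package estimates local associations, not
  causal policy effects.
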