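---
title: "Methods: gridded ozone health impacts and ensemble uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gridded ozone health impacts and ensemble uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(o3hia)
```

## The problem

Climate change perturbs the meteorology that controls surface ozone
formation, so even with anthropogenic precursor emissions held fixed, a
future climate implies different ozone exposure — higher in some regions,
lower in others. Translating a simulated ozone change into health terms
requires combining three independently uncertain ingredients: the gridded
ozone fields from a linked climate–air quality modeling system, a projection
of the exposed population (its size, spatial pattern and age structure), and
an epidemiological concentration–response (C–R) function. `o3hia`
implements the per-grid-cell computation and the ensemble analysis that
measures how much each ingredient moves the answer.

## The health impact function

C–R functions from the time-series literature are log-linear,
$y = B e^{\beta x}$, with $x$ the ozone metric (here the ozone-season mean
of the daily maximum 8-hour average, MDA8) and $\beta$ the per-ppb log-rate
coefficient. The induced change for a concentration change
$\Delta x = x_1 - x_0$ is

$$\Delta y = y_0\left(e^{\beta \Delta x} - 1\right),$$

where the baseline incidence $y_0$ is the event rate times the exposed
population, scaled to the season. The intercept $B$ cancels, which is why
`crf()` does not store it. `health_impact()` evaluates this exactly (via
`expm1()`, accurate for the small $\beta\Delta x$ typical here); at
realistic magnitudes ($|\beta \Delta x| < 0.01$) the function is nearly
linear, and the test suite checks the Taylor remainder bound
$|\Delta y - y_0\beta\Delta x| \le \tfrac12 y_0 (\beta\Delta x)^2
e^{|\beta\Delta x|}$.

**Seasonal convention.** The climate–air quality simulations deliver a
seasonal-mean MDA8, which is applied to every day of the season. We define
$y_0(\text{season}) = \text{annual rate} \times \text{persons} \times
n_{days}/365$ with $n_{days} = 92$ for June–August. This is the unique
convention for which applying the impact function day by day and summing
equals a single seasonal evaluation — an identity the tests verify
algebraically. `o3_season()` makes $n_{days}$ tunable for longer-season
sensitivity runs (e.g. 153 days for May–September); impacts scale
proportionally through $y_0$.

**Cell computation.** `cell_impacts()` uses one national $\beta$ in every
cell, but builds $y_0$ from county age-specific rates, the county
population inside the C–R function's age range, and county-to-cell
allocation weights. Cells spanning several counties therefore get a
population-weighted mixture of county rates. Counties or cells with zero
population contribute exactly zero cases, never `NaN`.

## Exposure processing

* `compute_mda8()` takes the maximum of rolling 8-hour means over a 24-hour
  day. We use the 17 complete within-day windows (start hours 0–16) and do
  not spill into the next day; no cross-midnight rule is imposed by the
  metric's common definition at seasonal-mean precision, and the choice is
  documented here so it can be revisited if hourly archives with
  cross-midnight windows are used.
* `remap()` is conservative area-weighted regridding on rectangular
  longitude/latitude cells under a plate-carrée approximation — adequate at
  the ~30 km scale of the analysis grid and free of projection-library
  dependencies. Nearest-neighbour remapping was rejected as
  non-conservative. Target cells with no source overlap are explicit `NA`s
  with a warning, and are excluded from downstream sums.
* Region assignment splits the conterminous U.S. at 100°W and 36.5°N into
  Northeast, Southeast and West by cell center. Boundary ties: centers
  exactly on 100°W go West; centers exactly on 36.5°N east of the split go
  Northeast (a north-inclusive reading of "north of"). The three labels
  partition any grid.

## Population and incidence

Age bins are half-open $[lo, hi)$ in years; "65 and older" is $[65,
\infty)$. Partial bins are split assuming uniform age density within the
bin — the standard demographic approximation. Open-ended top bins get an
effective upper bound (`open_age_cap`, default 100 years) so proportional
splits and the additivity property
$\text{slice}(a,b) + \text{slice}(b,c) = \text{slice}(a,c)$ are well
defined; results are insensitive to the cap for any C–R age range bounded
below 100.

County mortality rates are pooled over multiple years of death counts
(deaths divided by person-years; three years is the conventional span for
stability) and projected to the future year by multiplying each age bin by
a national life-table ratio. The ratios are inputs — published analyses
derive them from census life tables but do not print them — and the
synthetic generator draws them in $(0.5, 1.0]$, emulating projected
mortality decline. Hospitalization and ER-visit rates are regional,
broadcast to every member county, and held at base-year values: no
credible trend projections exist for them. ICD-9 cause groupings are the
caller's concern; the package takes pre-aggregated event counts.

## C–R library

Coefficients estimated against other ozone metrics (24-h mean, 1-h max)
are converted to MDA8 by a multiplicative ratio applied to both $\beta$
and its standard error. Ratios are a configuration table;
`default_metric_conversions()` ships illustrative values (1 ppb 24-h mean
≡ 0.67 ppb MDA8; 1-h max 0.90) used only by synthetic fixtures and labeled
non-authoritative — real analyses should supply study-specific ratios.

`pool_crf()` combines multiple studies for one endpoint:
inverse-variance fixed-effect weights $w_i = 1/se_i^2$, or
DerSimonian–Laird random effects, adding the moment estimate
$\hat\tau^2 = \max\{0, (Q - (k-1)) / (\sum w_i - \sum w_i^2/\sum w_i)\}$
to each variance. Random effects is the default, matching the usual
treatment of multi-city mortality studies; both $\beta$-level methods are
provided because Monte-Carlo pooling of full coefficient distributions
(the other historical convention) adds nothing at the point-estimate level
this package reports. The $\hat\tau^2$ truncation at zero is the standard
non-negativity constraint. Tests cross-check both methods against
`metafor`.

## Ensemble analysis

`run_factorial()` evaluates the pipeline once per (modeling system, C–R
study, population projection) combination. With one observation per cell
the balanced three-way ANOVA of `anova_decompose()` has no residual term;
the three-way interaction is reported as its own source, so the seven
sums of squares add exactly to the total and the degrees of freedom to
$n-1$. The decomposition is computed with `stats::aov()` and verified in
the tests against a brute-force cell-mean-contrast oracle; balance makes
it unique, and permutation invariance is asserted.

The package ships the published 105-entry national nonaccidental-mortality
ensemble as CSV (`national_mortality_ensemble()`). Its values are rounded
to the nearest 10 deaths as printed; running the decomposition on them
recovers the published percent-of-total shares at integer precision
(checked by the test suite), indicating the published decomposition was
itself computed on rounded values — so integer-percent agreement is the
right comparison. Reporting-level rounding in this package
(`round_report()`) rounds halves away from zero, treating signed death
counts symmetrically, and is never applied mid-pipeline.

`population_weighted_cdf()` gives the weighted empirical CDF of per-cell
ozone change with weights proportional to persons; the share of the
population facing an ozone increase is $1 - \text{CDF}(0)$, computed as
the weight above zero (ties at exactly zero count as non-increase).

## The synthetic generator

`simulate_scenario()` emulates the statistical structure of the real
inputs so every stage runs without downloads:

* **Exposure deltas** (`generate_exposure()`): a truncated-normal baseline
  field (default mean 48, SD 6 ppb — typical summer seasonal-mean MDA8
  magnitudes) plus per-region mean changes and spatially correlated noise.
  Correlation is imposed by a moving-average smoother of white noise with
  half-width `corr_length` cells (circular edges), rescaled to the profile's
  noise SD — a deliberately simple stand-in for geostatistical simulation.
  The seven default profiles qualitatively reproduce the observed ensemble
  pattern: several all-positive systems, two with a Northeast decrease and
  Southeast increase, one reversed.
* **Populations** (`generate_population()`): one synthetic county per grid
  cell, scenario totals allocated with lognormal spatial weights (emulating
  clustering), identical 5-year age structures per county constructed so the
  65+ share matches the scenario exactly. The five default scenarios span
  the real projections' spread: a smaller-but-older projection (386.7M, 26%
  aged 65+), a larger-but-younger one (424.8M, 21%), an intermediate case,
  a trend extrapolation, and a base-year population (281.4M, 12.4%) that
  isolates the climate signal from population change.
* **Incidence** (`generate_incidence()`): Gompertz-like mortality rates
  rising strictly with age, county-level lognormal scaling constant across
  ages (preserving the gradient), and life-table ratios in $(0.5, 1.0]$.
* **C–R fixtures** (`default_crf_fixtures()`): three mortality
  coefficients with the literature's typical spread (one several-fold
  steeper), explicitly non-authoritative.

All generators are pure functions of (configuration, seed).

**What the synthetic data does not emulate** — and hence what passing
tests do not show about real data: real chemistry-driven spatial structure
in $\Delta O_3$ (fronts, urban plumes, coastal gradients), real county
geographies and within-county population heterogeneity, spatial
correlation between population density and ozone change, age-varying
county rate profiles, and any calibration of the C–R fixtures. Synthetic
ensemble totals are therefore never compared against the published table;
only structural properties (balance, conservation, monotonicity,
closed-form recovery) are asserted on synthetic runs.

## Problem sizes and numerics

The default synthetic scenario uses a 24 × 12 grid (288 cells, one county
each), 18 age bins, 7 systems, 5 projections and 3 C–R functions; the full
105-run factorial completes in a few seconds, which keeps the whole suite
quick while leaving every code path exercised at realistic shape. Monte
Carlo checks of the exposure generator use a 10,000-cell grid, with the
standard error inflated by the smoothing footprint (the noise is
correlated by construction). Conservation properties are asserted at
1e-8 relative or tighter; the closed-form end-to-end recovery at 1e-6
relative.

## Known limitations

* Point estimates only: the standard errors carried by `crf` objects feed
  pooling but no confidence intervals are propagated to impact totals.
* Plate-carrée cell areas bias area weights slightly at continental
  latitude spans; immaterial at 30-km cells but not intended for coarse
  global grids.
* No economic valuation, no PM2.5 pathway, and no probabilistic weighting
  across modeling systems — ensemble members are deliberately treated as
  equally plausible "what if" scenarios.
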