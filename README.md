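# o3hia

Climate change alters meteorology and atmospheric chemistry, and with them
surface ozone. `o3hia` estimates the human health consequences of such
climate-driven ozone changes on a grid, and — just as importantly — quantifies
how much the answer depends on the modeling choices: which linked climate–air
quality modeling system produced the ozone fields, which population projection
describes the exposed population, and which epidemiological
concentration–response function links ozone to health events. It is aimed at
environmental health scientists and air-quality analysts who want a
transparent, desk-scale re-implementation of the grid-cell computation that
benefits-analysis systems such as the U.S. EPA's BenMAP perform, plus the
ensemble machinery around it.

## The model

Epidemiological studies of ozone usually report log-linear
concentration–response (C–R) functions,

```
y = B exp(βx)
```

where *x* is the ambient ozone level (here the June–August seasonal mean of
the daily maximum 8-hour average, MDA8, in ppb), *y* the incidence of the
health endpoint, and *β* the per-ppb log-rate coefficient. For a simulated
ozone change Δ*x* = *x*₁ − *x*₀ between a baseline (ca. 2000) and a future
(ca. 2050) climate, the induced change in events is the health impact
function

```
Δy = y₀ [exp(βΔx) − 1]
```

with baseline incidence *y*₀ = rate × exposed population, scaled to the
92-day ozone season. `o3hia` evaluates this per grid cell — one national *β*,
but population and county baseline rates as location-specific as the inputs
allow — and aggregates to three regions (Northeast / Southeast / West, split
at 100°W and 36.5°N) and the nation. Around the engine sit:

* **exposure tools** — MDA8 computation, seasonal means, area-weighted
  regridding, exposure deltas;
* **population tools** — age-structured county projections, age slicing,
  county-to-cell allocation;
* **incidence tools** — county mortality rates from multi-year death counts,
  life-table projection to the future year, regional morbidity rates;
* **C–R tools** — metric conversion, fixed-effect and DerSimonian–Laird
  random-effects pooling;
* **ensemble tools** — a full factorial over systems × studies × projections,
  balanced three-way ANOVA variance decomposition, range summaries, and
  population-weighted exposure-change CDFs;
* **a synthetic-data generator** that emulates every input (regionally
  patterned ozone deltas, population scenarios differing in size and age
  skew, age-graded mortality rates), so the whole pipeline runs end to end
  with no external data.

A published 105-entry ensemble of national summertime ozone-related
nonaccidental mortality estimates (7 modeling systems × 3 studies × 5
population projections, rounded to the nearest 10 deaths) ships as plain CSV
and exercises the ensemble layer on real numbers.

## Worked example

```r
library(o3hia)

pub <- national_mortality_ensemble()
summarize_range(pub)
#> # A tibble: 2 × 5
#>   extreme system     study           population deaths
#>   <chr>   <chr>      <chr>           <chr>       <dbl>
#> 1 min     WSU        Ito et al. 2005 ICLUS-A1     -650
#> 2 max     Illinois-1 Ito et al. 2005 ICLUS-A1     2560

tidy(anova_decompose(pub))
#> # A tibble: 7 × 4
#>   source                         df     sumsq percent
#>   <chr>                       <int>     <dbl>   <dbl>
#> 1 system                          6 24271499.   47.9
#> 2 study                           2  9055636.   17.9
#> 3 population                      4  2108558.    4.16
#> 4 system x study                 12 10495284.   20.7
#> 5 system x population            24  2641882.    5.21
#> 6 study x population              8   921745.    1.82
#> 7 system x study x population    48  1165135.    2.30
```

The ensemble spans roughly 650 deaths avoided to 2,560 deaths attributable to
climate-driven ozone change, and the choice of climate–air quality modeling
system alone accounts for ~48% of the total variability — the single largest
source — with the study (C–R function) and its interaction with the system
contributing ~18% and ~21%.

The same analysis runs end to end on synthetic inputs:

```r
sc  <- simulate_scenario(seed = 1)       # 288-cell grid, 7 systems, 5 pops, 3 C-R
ens <- run_factorial(sc$systems, sc$populations, sc$crfs, sc$rates, sc$season)
glance(anova_decompose(ens))
#> # A tibble: 1 × 4
#>    total_ss     n df_total largest_source
#>       <dbl> <int>    <int> <chr>
#> 1 48462071.   105      104 system

popf <- allocate_to_grid(sc$populations[["proj-larger"]]$projection,
                         sc$populations[["proj-larger"]]$weights)
cdf  <- population_weighted_cdf(sc$systems[["sysA-high"]], popf)
attr(cdf, "fraction_increase")
#> [1] 0.9938793
```

`autoplot()` methods produce ggplot figures for cell-level impact maps,
ANOVA decompositions and exposure CDFs; `tidy()`/`glance()` give tabular
summaries.

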