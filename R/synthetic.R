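# Synthetic inputs emulating the statistical structure the analysis assumes:
# regionally patterned ozone-change fields, age-structured population
# projections differing in size and age skew, age-graded mortality rates.
# All generators are pure functions of (configuration, seed).

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default synthetic modeling-system profiles
#'
#' Seven pseudo modeling systems whose regional mean ozone changes follow
#' the qualitative pattern seen across linked climate-air quality
#' simulations: several systems with increases everywhere, two with a
#' decrease in the Northeast accompanied by a Southeast increase, and one
#' with the reverse pattern. Magnitudes (ppb) are illustrative, not fitted
#' to any simulation archive.
#'
#' @return Tibble `system`, `d_northeast`, `d_southeast`, `d_west` (mean
#'   seasonal ozone change per region, ppb), `noise_sd` (ppb),
#'   `corr_length` (cells).
#' @export
default_system_profiles <- function() {
  tibble::tribble(
    ~system,      ~d_northeast, ~d_southeast, ~d_west, ~noise_sd, ~corr_length,
    "sysA-high",   2.5,          2.0,          1.2,     0.8,       2,
    "sysB-high",   2.3,          1.8,          1.0,     0.8,       2,
    "sysC-mid",    2.2,          1.6,          0.6,     0.8,       2,
    "sysD-mid",    1.2,          0.8,          0.5,     0.8,       2,
    "sysE-dipole", -0.8,         0.9,          0.2,     0.8,       2,
    "sysF-dipole", -0.6,         0.7,         -0.2,     0.8,       2,
    "sysG-reverse", 1.0,        -1.5,          0.3,     0.8,       2
  )
}

#' Default synthetic population scenarios
#'
#' Five scenarios spanning the kind of spread real 2050 projections show:
#' a larger-but-younger projection, a smaller-but-older one, an
#' intermediate case, a trend extrapolation, and a no-growth scenario that
#' keeps the base-year population (used to isolate the climate signal from
#' population change). Totals are persons; `share_65plus` is the fraction
#' aged 65 and over.
#'
#' @return Tibble `name`, `total`, `share_65plus`.
#' @export
default_population_scenarios <- function() {
  tibble::tribble(
    ~name,              ~total,    ~share_65plus,
    "proj-older",       386.7e6,   0.26,
    "proj-larger",      424.8e6,   0.21,
    "proj-mid",         405.0e6,   0.23,
    "proj-trend",       364.0e6,   0.24,
    "base-year-2000",   281.4e6,   0.124
  )
}

#' Synthetic concentration-response fixtures
#'
#' Three mortality C-R functions with the spread typical of the
#' epidemiological literature (one several times steeper than the others).
#' Coefficients are illustrative fixtures for exercising the pipeline, not
#' estimates from any study.
#'
#' @return A C-R tibble (3 rows, endpoint "nonaccidental mortality",
#'   metric MDA8).
#' @export
default_crf_fixtures <- function() {
  dplyr::bind_rows(
    crf("synth-low",   "nonaccidental mortality", "MDA8", 0.00040, 0.00013),
    crf("synth-high",  "nonaccidental mortality", "MDA8", 0.00180, 0.00060),
    crf("synth-mid",   "nonaccidental mortality", "MDA8", 0.00060, 0.00020)
  )
}

# moving-average smoother imposing spatial correlation; circular edges keep
# the field mean-zero and stationary
smooth_matrix <- function(m, corr_length) {
  run_filter <- function(v, L) {
    L <- min(L, floor((length(v) - 1) / 2))
    if (L < 1) return(v)
    k <- rep(1 / (2 * L + 1), 2 * L + 1)
    as.numeric(stats::filter(v, k, circular = TRUE))
  }
  if (corr_length < 1) return(m)
  sm <- apply(m, 2, run_filter, L = corr_length)
  sm <- t(apply(sm, 1, run_filter, L = corr_length))
  matrix(sm, nrow = nrow(m))
}

#' Generate a synthetic exposure delta for one modeling system
#'
#' Draws a baseline seasonal-mean MDA8 field (truncated at zero) and adds
#' the system's regional mean change plus spatially correlated, mean-zero
#' noise to form the future field. Regional means are applied by cell
#' center via [assign_regions()]. Same seed, same output.
#'
#' @param profile One row of a system-profile tibble (see
#'   [default_system_profiles()]).
#' @param grid An `o3_grid` built by [make_grid()].
#' @param seed Integer seed.
#' @param baseline_mean,baseline_sd Baseline field distribution (ppb).
#' @return An `o3_delta`.
#' @export
generate_exposure <- function(profile, grid, seed,
                              baseline_mean = 48, baseline_sd = 6) {
  stopifnot(nrow(profile) == 1)
  nx <- attr(grid, "nx"); ny <- attr(grid, "ny")
  if (is.null(nx) || is.null(ny)) {
    stop("`grid` must carry nx/ny attributes (build it with make_grid())",
         call. = FALSE)
  }
  regions <- assign_regions(grid)
  mu <- c(Northeast = profile$d_northeast,
          Southeast = profile$d_southeast,
          West = profile$d_west)[regions$region]
  with_seed(seed, {
    baseline <- pmax(stats::rnorm(nrow(grid), baseline_mean, baseline_sd), 0)
    noise <- rep(0, nrow(grid))
    if (profile$noise_sd > 0) {
      z <- smooth_matrix(matrix(stats::rnorm(nx * ny), nrow = nx, ncol = ny),
                         profile$corr_length)
      z <- as.numeric(z)
      z <- (z - mean(z)) / stats::sd(z) * profile$noise_sd
      noise <- z
    }
    make_delta(
      tibble::tibble(cell_id = grid$cell_id, value = baseline),
      tibble::tibble(cell_id = grid$cell_id, value = baseline + unname(mu) + noise)
    )
  })
}

#' Generate a synthetic age-structured population projection
#'
#' Builds one synthetic county per grid cell, distributes the scenario
#' total over counties with lognormal spatial weights (emulating population
#' clustering), and gives every county the same 5-year age structure
#' constructed so the 65-and-over share matches `share_65plus` exactly.
#' County-to-cell allocation weights are 1 (each county coincides with its
#' cell).
#'
#' @param total Total persons, > 0.
#' @param share_65plus Fraction aged 65+, in (0, 1).
#' @param grid An `o3_grid`.
#' @param seed Integer seed.
#' @param name Scenario name attached as an attribute.
#' @return A list with `projection` (tibble `county_id`, `age_lo`,
#'   `age_hi`, `count`), `weights` (tibble `county_id`, `cell_id`,
#'   `weight`) and `name`.
#' @export
generate_population <- function(total, share_65plus, grid, seed,
                                name = "synthetic") {
  if (total <= 0) stop("`total` must be > 0", call. = FALSE)
  if (share_65plus <= 0 || share_65plus >= 1) {
    stop("`share_65plus` must be in (0, 1)", call. = FALSE)
  }
  age_lo <- c(seq(0, 80, by = 5), 85)
  age_hi <- c(seq(5, 85, by = 5), Inf)
  # declining-with-age template below 65, steeper decline above
  mid <- ifelse(is.finite(age_hi), (age_lo + age_hi) / 2, 90)
  template <- exp(-0.012 * mid)
  young <- age_lo < 65
  shares <- numeric(length(age_lo))
  shares[young] <- template[young] / sum(template[young]) * (1 - share_65plus)
  shares[!young] <- template[!young] / sum(template[!young]) * share_65plus
  with_seed(seed, {
    w <- stats::rlnorm(nrow(grid), 0, 1)
    w <- w / sum(w)
    cty_total <- total * w
    projection <- tidyr::expand_grid(
      county_id = grid$cell_id,
      tibble::tibble(age_lo = age_lo, age_hi = age_hi, share = shares)
    )
    projection$count <- cty_total[match(projection$county_id, grid$cell_id)] *
      projection$share
    projection$share <- NULL
    out <- list(
      projection = tibble::as_tibble(projection),
      weights = tibble::tibble(county_id = grid$cell_id,
                               cell_id = grid$cell_id, weight = 1),
      name = name
    )
    out
  })
}

#' Generate synthetic baseline incidence rates and life-table ratios
#'
#' Mortality rates rise strictly with age following a Gompertz-like curve,
#' scaled by a county-level lognormal factor (constant across ages within
#' a county, preserving the age gradient). Life-table ratios emulate
#' projected declining mortality: one ratio per age bin drawn in
#' (0.5, 1.0].
#'
#' @param county_ids Vector of county identifiers.
#' @param seed Integer seed.
#' @param endpoint Endpoint label.
#' @return A list with `rates` (incidence table) and `ratios` (tibble
#'   `age_lo`, `age_hi`, `ratio`).
#' @export
generate_incidence <- function(county_ids, seed,
                               endpoint = "nonaccidental mortality") {
  age_lo <- c(seq(0, 80, by = 5), 85)
  age_hi <- c(seq(5, 85, by = 5), Inf)
  mid <- ifelse(is.finite(age_hi), (age_lo + age_hi) / 2, 90)
  base_rate <- 1e-4 * exp(0.075 * mid)
  with_seed(seed, {
    cty_factor <- stats::rlnorm(length(county_ids), 0, 0.15)
    rates <- tidyr::expand_grid(
      location_id = county_ids,
      tibble::tibble(age_lo = age_lo, age_hi = age_hi, base = base_rate)
    )
    rates$rate <- rates$base * cty_factor[match(rates$location_id, county_ids)]
    rates$base <- NULL
    rates <- dplyr::bind_cols(tibble::tibble(endpoint = endpoint), rates)
    ratios <- tibble::tibble(
      age_lo = age_lo, age_hi = age_hi,
      ratio = stats::runif(length(age_lo), 0.5, 1.0)
    )
    list(rates = tibble::as_tibble(rates), ratios = ratios)
  })
}

#' Assemble a complete synthetic scenario
#'
#' Builds everything one end-to-end run needs: the analysis grid and
#' region mask, one exposure delta per synthetic modeling system, the
#' population projections with allocation weights, the baseline incidence
#' table (projected to the future year with synthetic life-table ratios),
#' and the C-R fixtures. Deterministic given `seed`.
#'
#' @param nx,ny Grid dimensions (default 24 x 12 over the conterminous-US
#'   bounding box).
#' @param seed Integer seed driving all generators.
#' @param profiles System profiles (default [default_system_profiles()]).
#' @param pop_scenarios Population scenarios (default
#'   [default_population_scenarios()]).
#' @param crfs C-R functions (default [default_crf_fixtures()]).
#' @return A list `grid`, `regions`, `systems` (named list of deltas),
#'   `populations` (named list of projection+weights), `rates` (projected),
#'   `rates_base`, `ratios`, `crfs`, `season`.
#' @export
simulate_scenario <- function(nx = 24, ny = 12, seed = 1,
                              profiles = default_system_profiles(),
                              pop_scenarios = default_population_scenarios(),
                              crfs = default_crf_fixtures()) {
  grid <- make_grid(nx, ny)
  regions <- assign_regions(grid)
  n_sub <- nrow(profiles) + nrow(pop_scenarios) + 1
  subseeds <- with_seed(seed, sample.int(2^30, n_sub))
  systems <- stats::setNames(
    lapply(seq_len(nrow(profiles)), function(i) {
      generate_exposure(profiles[i, ], grid, subseeds[i])
    }),
    profiles$system
  )
  populations <- stats::setNames(
    lapply(seq_len(nrow(pop_scenarios)), function(i) {
      generate_population(pop_scenarios$total[i],
                          pop_scenarios$share_65plus[i],
                          grid, subseeds[nrow(profiles) + i],
                          name = pop_scenarios$name[i])
    }),
    pop_scenarios$name
  )
  inc <- generate_incidence(grid$cell_id, subseeds[n_sub])
  rates_2050 <- project_rates(inc$rates, inc$ratios)
  list(
    grid = grid, regions = regions, systems = systems,
    populations = populations,
    rates = rates_2050, rates_base = inc$rates, ratios = inc$ratios,
    crfs = crfs, season = o3_season()
  )
}
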