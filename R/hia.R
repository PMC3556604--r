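#' Ozone season specification
#'
#' The exposure season over which seasonal-mean MDA8 is applied day by day.
#' The default is climatological summer, June-August (92 days), matching
#' the season simulated by the climate-air quality modeling systems; a
#' longer season (e.g. May-September, 153 days) can be supplied for
#' sensitivity runs.
#'
#' @param n_days Number of days in the season.
#' @param label Season label.
#' @return A list with `n_days` and `label`.
#' @export
o3_season <- function(n_days = 92, label = "JJA") {
  stopifnot(is.numeric(n_days), n_days >= 1)
  list(n_days = n_days, label = label)
}

#' The log-linear health impact function
#'
#' Evaluates `delta_y = y0 * (exp(beta * delta_x) - 1)`: the change in
#' health-event counts induced by a concentration change `delta_x` (ppb)
#' acting on a baseline incidence `y0` (events over the exposure period)
#' through a log-linear concentration-response coefficient `beta` (per
#' ppb). Negative `delta_x` yields negative `delta_y` (events avoided)
#' when `beta > 0`.
#'
#' @param y0 Baseline incidence, events over the period; >= 0. Vectorized.
#' @param beta C-R coefficient per ppb.
#' @param delta_x Concentration change, ppb. Vectorized.
#' @return `delta_y`, events (possibly negative).
#' @examples
#' health_impact(1000, 0.000795, 5)    # ~3.98 additional events
#' health_impact(100, 0.001, -10)      # ~-1 avoided event
#' @export
health_impact <- function(y0, beta, delta_x) {
  if (any(!is.finite(y0)) || any(!is.finite(beta)) || any(!is.finite(delta_x))) {
    stop("`y0`, `beta` and `delta_x` must all be finite", call. = FALSE)
  }
  if (any(y0 < 0)) stop("`y0` must be non-negative", call. = FALSE)
  y0 * expm1(beta * delta_x)
}

#' Grid-cell attributable cases for one exposure delta and C-R function
#'
#' The per-cell computation at the core of the pipeline: for each grid
#' cell, the seasonal baseline incidence is assembled from county
#' age-specific rates, the county population in the C-R function's age
#' range, and the county-to-cell allocation weights,
#' `y0(cell) = sum over counties of
#'    weight * persons_in_range * rate * n_days/365`,
#' and the attributable change is `delta_y = y0 * (exp(beta * delta_x) - 1)`.
#' One national coefficient `beta` is used in every cell, while population
#' and baseline rates are as location-specific as the inputs allow.
#'
#' @param delta An `o3_delta` (see [make_delta()]).
#' @param pop Population projection tibble `county_id`, `age_lo`, `age_hi`,
#'   `count`.
#' @param weights County-to-cell weights `county_id`, `cell_id`, `weight`.
#' @param rates Incidence table `endpoint`, `location_id`, `age_lo`,
#'   `age_hi`, `rate` (annual). Each population age bin inside the C-R age
#'   range must be covered by a rate bin for its county.
#' @param f A one-row C-R function (see [crf()]); its metric must be MDA8,
#'   the metric of the exposure fields.
#' @param season An [o3_season()].
#' @param open_age_cap Effective upper age for open-ended bins (years).
#' @return A tibble of class `o3_hia` with columns `cell_id`, `delta`
#'   (ppb), `y0` (baseline seasonal events) and `delta_cases`; attributes
#'   `endpoint`, `study`, `season`.
#' @export
cell_impacts <- function(delta, pop, weights, rates, f, season = o3_season(),
                         open_age_cap = 100) {
  stopifnot(inherits(delta, "o3_delta") || all(c("cell_id", "delta") %in% names(delta)),
            nrow(f) == 1)
  if (f$metric != "MDA8") {
    stop("C-R function metric must be MDA8 (convert with convert_metric())",
         call. = FALSE)
  }
  rates_e <- rates[rates$endpoint == f$endpoint, , drop = FALSE]
  if (nrow(rates_e) == 0) {
    stop("no rates for endpoint '", f$endpoint, "'", call. = FALSE)
  }

  # persons of each county age bin falling inside the C-R age range
  lo <- min(f$age_lo, open_age_cap)
  hi <- min(f$age_hi, open_age_cap)
  blo <- pop$age_lo
  bhi <- pmin(pop$age_hi, open_age_cap)
  frac <- pmax(pmin(hi, bhi) - pmax(lo, blo), 0) / pmax(bhi - blo, .Machine$double.eps)
  eff <- tibble::tibble(county_id = pop$county_id,
                        age_lo = pop$age_lo, age_hi = pop$age_hi,
                        persons = frac * pop$count)
  eff <- eff[eff$persons > 0, , drop = FALSE]

  # rate lookup: exact bin match first, then any rate bin covering the
  # population bin (coarser morbidity bins)
  exact <- dplyr::left_join(
    eff,
    dplyr::rename(rates_e[c("location_id", "age_lo", "age_hi", "rate")],
                  county_id = "location_id"),
    by = c("county_id", "age_lo", "age_hi")
  )
  eff$rate <- exact$rate
  todo <- which(is.na(eff$rate))
  if (length(todo) > 0) {
    ri <- mapply(function(cty, alo, ahi) {
      hit <- which(rates_e$location_id == cty &
                     rates_e$age_lo <= alo & rates_e$age_hi >= ahi)
      if (length(hit) == 0) NA_integer_ else hit[1]
    }, eff$county_id[todo], eff$age_lo[todo], eff$age_hi[todo])
    eff$rate[todo] <- rates_e$rate[ri]
  }
  if (anyNA(eff$rate)) {
    miss <- unique(eff$county_id[is.na(eff$rate)])
    stop("no '", f$endpoint, "' rate covering an age bin for county: ",
         paste(utils::head(miss, 10), collapse = ", "), call. = FALSE)
  }

  cty_y0 <- dplyr::summarise(
    dplyr::group_by(eff, .data$county_id),
    y0_annual = sum(.data$persons * .data$rate),
    .groups = "drop"
  )
  alloc <- dplyr::inner_join(weights, cty_y0, by = "county_id")
  cell_y0 <- dplyr::summarise(
    dplyr::group_by(alloc, .data$cell_id),
    y0 = sum(.data$weight * .data$y0_annual) * season$n_days / 365,
    .groups = "drop"
  )

  out <- dplyr::left_join(delta[c("cell_id", "delta")], cell_y0, by = "cell_id")
  out$y0[is.na(out$y0)] <- 0
  out$delta_cases <- health_impact(out$y0, f$beta, out$delta)
  out <- tibble::as_tibble(out)
  attr(out, "endpoint") <- f$endpoint
  attr(out, "study") <- f$study
  attr(out, "season") <- season
  class(out) <- c("o3_hia", class(out))
  out
}

#' Aggregate cell impacts to regions and the national total
#'
#' Sums attributable cases over cells by region; the national total equals
#' the sum of the regional totals and of all cells exactly. All cells in
#' the result must be covered by the region mask.
#'
#' @param result An `o3_hia` from [cell_impacts()], or any tibble with
#'   `cell_id` and `delta_cases`.
#' @param regions Region mask `cell_id`, `region` (see [assign_regions()]).
#' @return A tibble of class `o3_hia_summary`: one row per region plus a
#'   `"National"` row, column `delta_cases`.
#' @export
aggregate_impacts <- function(result, regions) {
  stopifnot(all(c("cell_id", "delta_cases") %in% names(result)),
            all(c("cell_id", "region") %in% names(regions)))
  uncovered <- setdiff(result$cell_id, regions$cell_id)
  if (length(uncovered) > 0) {
    stop("cells not covered by the region mask: ",
         paste(utils::head(uncovered, 10), collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::inner_join(result[c("cell_id", "delta_cases")], regions,
                              by = "cell_id")
  reg <- dplyr::summarise(dplyr::group_by(joined, .data$region),
                          delta_cases = sum(.data$delta_cases), .groups = "drop")
  out <- dplyr::bind_rows(
    reg,
    tibble::tibble(region = "National", delta_cases = sum(reg$delta_cases))
  )
  class(out) <- c("o3_hia_summary", class(out))
  out
}

#' Round impacts for reporting
#'
#' Rounds to the nearest multiple of 10, halves away from zero (so 148 ->
#' 150, -275 -> -280, -274 -> -270). Applied only at the reporting layer;
#' all aggregation is done on unrounded values.
#'
#' @param value Numeric vector of case counts.
#' @param nearest Rounding unit (default 10).
#' @return Rounded values.
#' @export
round_report <- function(value, nearest = 10) {
  stopifnot(all(is.finite(value)))
  sign(value) * floor(abs(value) / nearest + 0.5) * nearest
}

#' @exportS3Method generics::tidy
tidy.o3_hia <- function(x, regions = NULL, ...) {
  if (is.null(regions)) {
    return(tibble::as_tibble(x)[c("cell_id", "delta", "y0", "delta_cases")])
  }
  out <- aggregate_impacts(x, regions)
  tibble::as_tibble(out)
}

#' @exportS3Method generics::glance
glance.o3_hia <- function(x, ...) {
  tibble::tibble(
    endpoint = attr(x, "endpoint"),
    study = attr(x, "study"),
    n_cells = nrow(x),
    national = sum(x$delta_cases),
    national_rounded = round_report(sum(x$delta_cases))
  )
}

#' Map of per-cell attributable cases
#'
#' @param object An `o3_hia`.
#' @param grid The `o3_grid` the result lives on (supplies coordinates).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.o3_hia <- function(object, grid, ...) {
  df <- dplyr::inner_join(tibble::as_tibble(object),
                          grid[c("cell_id", "lon", "lat")], by = "cell_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, fill = .data$delta_cases)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  fill = "Attributable\ncases",
                  title = attr(object, "endpoint")) +
    ggplot2::theme_minimal()
}
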