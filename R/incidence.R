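#' County age-specific mortality rates from death counts
#'
#' Pools several years of death counts and populations (the analysis uses
#' three years for stability) and returns annual rates: total deaths divided
#' by total person-years, per county and age bin.
#'
#' @param deaths Tibble `county_id`, `age_lo`, `age_hi`, `year`, `deaths`.
#' @param population Tibble `county_id`, `age_lo`, `age_hi`, `year`,
#'   `persons` covering the same county/age/year combinations.
#' @param endpoint Endpoint label attached to the output (default
#'   "nonaccidental mortality").
#' @return An incidence table: tibble `endpoint`, `location_id`, `age_lo`,
#'   `age_hi`, `rate` (events per person per year).
#' @export
county_mortality_rates <- function(deaths, population,
                                   endpoint = "nonaccidental mortality") {
  stopifnot(all(c("county_id", "age_lo", "age_hi", "year", "deaths") %in% names(deaths)),
            all(c("county_id", "age_lo", "age_hi", "year", "persons") %in% names(population)))
  key <- c("county_id", "age_lo", "age_hi")
  d <- dplyr::summarise(dplyr::group_by(deaths, dplyr::across(dplyr::all_of(key))),
                        deaths = sum(.data$deaths), .groups = "drop")
  p <- dplyr::summarise(dplyr::group_by(population, dplyr::across(dplyr::all_of(key))),
                        person_years = sum(.data$persons), .groups = "drop")
  tab <- dplyr::inner_join(d, p, by = key)
  bad <- tab$person_years <= 0 & tab$deaths > 0
  if (any(bad)) {
    stop("deaths recorded with zero population for county ",
         paste(utils::head(tab$county_id[bad], 5), collapse = ", "), call. = FALSE)
  }
  zero_pop <- tab$person_years <= 0 & tab$deaths == 0
  if (any(zero_pop)) {
    warning(sum(zero_pop), " county/age cell(s) have zero population; rate set to 0",
            call. = FALSE)
  }
  tibble::tibble(
    endpoint = endpoint,
    location_id = tab$county_id,
    age_lo = tab$age_lo,
    age_hi = tab$age_hi,
    rate = ifelse(tab$person_years > 0, tab$deaths / tab$person_years, 0)
  )
}

#' Project baseline mortality rates to a future year with life-table ratios
#'
#' Multiplies each county/age rate by a national age-specific ratio of
#' projected to base-period mortality (derived from national mortality life
#' tables, supplied as input). Rates for every age bin present in `rates`
#' must have a ratio.
#'
#' @param rates Incidence table (see [county_mortality_rates()]).
#' @param ratios Tibble `age_lo`, `age_hi`, `ratio` (dimensionless, > 0).
#' @return The incidence table with projected rates.
#' @export
project_rates <- function(rates, ratios) {
  stopifnot(all(c("age_lo", "age_hi", "ratio") %in% names(ratios)))
  if (any(!is.finite(ratios$ratio)) || any(ratios$ratio <= 0)) {
    stop("life-table ratios must be finite and > 0", call. = FALSE)
  }
  out <- dplyr::left_join(rates, ratios, by = c("age_lo", "age_hi"))
  if (anyNA(out$ratio)) {
    miss <- unique(out[is.na(out$ratio), c("age_lo", "age_hi")])
    stop("no life-table ratio for age bin(s): ",
         paste(sprintf("[%g,%g)", miss$age_lo, miss$age_hi), collapse = ", "),
         call. = FALSE)
  }
  out$rate <- out$rate * out$ratio
  out$ratio <- NULL
  out
}

#' Broadcast regional hospitalization / ER-visit rates to member counties
#'
#' Computes region-level annual rates (events / persons) and copies each
#' region's rate to every county in the region. Morbidity rates are held at
#' their base-year values: no projection is applied, since no reliable
#' trend projections exist for hospitalizations or ER visits. Cause
#' groupings (ICD-9 code sets) are the caller's concern: `events` is already
#' aggregated per region and endpoint.
#'
#' @param events Tibble `region`, `events` (annual event counts).
#' @param population Tibble `region`, `persons`.
#' @param county_regions Tibble `county_id`, `region` mapping every county
#'   to a region.
#' @param endpoint Endpoint label for the output table.
#' @param age_range Age range `c(lo, hi)` the endpoint applies to.
#' @return Incidence table with one row per county.
#' @export
regional_morbidity_rates <- function(events, population, county_regions,
                                     endpoint, age_range = c(0, Inf)) {
  stopifnot(all(c("region", "events") %in% names(events)),
            all(c("region", "persons") %in% names(population)),
            all(c("county_id", "region") %in% names(county_regions)))
  reg <- dplyr::inner_join(events, population, by = "region")
  reg$rate <- reg$events / reg$persons
  out <- dplyr::inner_join(county_regions, reg[c("region", "rate")], by = "region")
  uncovered <- setdiff(county_regions$county_id, out$county_id)
  if (length(uncovered) > 0 || anyNA(out$rate)) {
    stop("counties without a region rate: ",
         paste(utils::head(uncovered, 10), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(
    endpoint = endpoint,
    location_id = out$county_id,
    age_lo = age_range[1],
    age_hi = age_range[2],
    rate = out$rate
  )
}
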