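#' Persons in an age range of an age structure
#'
#' Sums counts over an age interval, taking fully covered bins whole and
#' splitting partially covered bins proportionally under a uniform-age-
#' within-bin assumption (the standard demographic approximation). Age
#' intervals are half-open `[lo, hi)` in years; "65 and older" is
#' `slice_age(x, 65, Inf)`. Open-ended top bins (`age_hi = Inf`) are given
#' an effective upper bound of `open_age_cap` years so proportional splits
#' remain well defined.
#'
#' @param structure Tibble with `age_lo`, `age_hi` (years, half-open bins,
#'   `Inf` allowed for the last) and `count` (persons).
#' @param lo,hi Age interval bounds in years, `lo <= hi`, non-negative.
#' @param open_age_cap Effective upper age for open-ended bins (years).
#' @return Persons in `[lo, hi)`, possibly fractional.
#' @examples
#' bins <- tibble::tibble(age_lo = c(0, 65), age_hi = c(65, Inf),
#'                        count = c(800, 200))
#' slice_age(bins, 65, Inf)  # 200
#' @export
slice_age <- function(structure, lo, hi, open_age_cap = 100) {
  stopifnot(all(c("age_lo", "age_hi", "count") %in% names(structure)))
  if (lo < 0 || hi < 0) stop("ages must be non-negative", call. = FALSE)
  if (lo > hi) stop("`lo` must be <= `hi`", call. = FALSE)
  blo <- structure$age_lo
  bhi <- pmin(structure$age_hi, open_age_cap)
  lo <- min(lo, open_age_cap)
  hi <- min(hi, open_age_cap)
  overlap <- pmax(pmin(hi, bhi) - pmax(lo, blo), 0)
  frac <- ifelse(bhi > blo, overlap / (bhi - blo), 0)
  sum(frac * structure$count)
}

#' Allocate a county population projection onto the analysis grid
#'
#' Distributes each county's persons in a requested age range over grid
#' cells using county-to-cell weights (the spatial allocation artifact;
#' each county's weights sum to 1). Totals are conserved exactly: persons
#' stay fractional, no rounding.
#'
#' @param pop Population projection: tibble `county_id`, `age_lo`, `age_hi`,
#'   `count`.
#' @param weights Tibble `county_id`, `cell_id`, `weight` with weights
#'   summing to 1 within each county (tolerance 1e-9).
#' @param age_range Length-2 numeric `c(lo, hi)` in years (half-open);
#'   default covers all ages.
#' @param open_age_cap Passed to [slice_age()].
#' @return Tibble `cell_id`, `value` (persons in the age range per cell).
#' @export
allocate_to_grid <- function(pop, weights, age_range = c(0, Inf),
                             open_age_cap = 100) {
  stopifnot(all(c("county_id", "age_lo", "age_hi", "count") %in% names(pop)),
            all(c("county_id", "cell_id", "weight") %in% names(weights)))
  missing_cty <- setdiff(unique(pop$county_id), unique(weights$county_id))
  if (length(missing_cty) > 0) {
    stop("counties missing from weights: ",
         paste(utils::head(missing_cty, 10), collapse = ", "), call. = FALSE)
  }
  wsum <- dplyr::summarise(dplyr::group_by(weights, .data$county_id),
                           s = sum(.data$weight), .groups = "drop")
  if (any(abs(wsum$s - 1) > 1e-9)) {
    stop("county weights must sum to 1 (county ",
         wsum$county_id[which.max(abs(wsum$s - 1))], " sums to ",
         format(wsum$s[which.max(abs(wsum$s - 1))]), ")", call. = FALSE)
  }
  by_cty <- dplyr::summarise(
    dplyr::group_by(pop, .data$county_id),
    persons = slice_age(dplyr::pick(dplyr::everything()),
                        age_range[1], age_range[2], open_age_cap),
    .groups = "drop"
  )
  alloc <- dplyr::inner_join(weights, by_cty, by = "county_id")
  dplyr::summarise(
    dplyr::group_by(alloc, .data$cell_id),
    value = sum(.data$weight * .data$persons),
    .groups = "drop"
  )
}

#' Per-county persons within an age range
#'
#' Convenience wrapper applying [slice_age()] county by county.
#'
#' @inheritParams allocate_to_grid
#' @return Tibble `county_id`, `persons`.
#' @export
county_age_totals <- function(pop, age_range = c(0, Inf), open_age_cap = 100) {
  dplyr::summarise(
    dplyr::group_by(pop, .data$county_id),
    persons = slice_age(dplyr::pick(dplyr::everything()),
                        age_range[1], age_range[2], open_age_cap),
    .groups = "drop"
  )
}
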