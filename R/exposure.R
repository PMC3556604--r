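#' Maximum daily 8-hour average ozone (MDA8)
#'
#' Computes the MDA8 for one day of hourly ozone concentrations: rolling
#' 8-hour averages are taken across the 24-hour period and their maximum is
#' returned. Only the 17 complete within-day windows (start hours 0-16) are
#' used; there is no spill-over into the next day.
#'
#' @param hourly Numeric vector of exactly 24 hourly concentrations (ppb),
#'   hour 0 first. All values must be finite and non-negative.
#' @return The MDA8 (ppb), a single number.
#' @examples
#' compute_mda8(rep(60, 24))          # 60
#' compute_mda8(0:23)                 # mean of hours 16..23 = 19.5
#' @export
compute_mda8 <- function(hourly) {
  if (length(hourly) != 24) {
    stop("`hourly` must have exactly 24 values, got ", length(hourly), call. = FALSE)
  }
  bad <- which(!is.finite(hourly) | hourly < 0)
  if (length(bad) > 0) {
    stop("`hourly` must be finite and non-negative; offending hour index (0-based): ",
         paste(bad - 1, collapse = ", "), call. = FALSE)
  }
  cs <- c(0, cumsum(hourly))
  windows <- (cs[9:25] - cs[1:17]) / 8
  max(windows)
}

#' Seasonal mean of daily MDA8 values
#'
#' The exposure metric driving the health impact function is the ozone-season
#' (default June-August) arithmetic mean of the daily MDA8.
#'
#' @param daily_mda8 Numeric vector of per-day MDA8 values (ppb), length >= 1.
#' @param season Season label carried through for bookkeeping; default "JJA".
#' @return The seasonal mean (ppb).
#' @export
seasonal_mean <- function(daily_mda8, season = "JJA") {
  if (length(daily_mda8) < 1) stop("need at least one daily value", call. = FALSE)
  if (any(!is.finite(daily_mda8))) stop("daily MDA8 values must be finite", call. = FALSE)
  mean(daily_mda8)
}

#' Remap a gridded field onto a target grid
#'
#' Each target-cell value is the overlap-area-weighted mean of the source
#' cells intersecting it. Overlap areas are computed on rectangular
#' longitude/latitude cells under a plate-carree approximation, which is
#' adequate at the ~30 km scale of the analysis grid. Target cells with no
#' source overlap are set to `NA` and a warning reports their count.
#'
#' @param field Tibble `cell_id`, `value` on `source_grid`.
#' @param source_grid,target_grid `o3_grid` objects (cell bounds in degrees).
#' @return Tibble `cell_id`, `value` on the target grid.
#' @export
remap <- function(field, source_grid, target_grid) {
  stopifnot(all(c("cell_id", "value") %in% names(field)))
  src <- dplyr::inner_join(
    source_grid[c("cell_id", "lon_w", "lon_e", "lat_s", "lat_n")],
    field[c("cell_id", "value")],
    by = "cell_id"
  )
  tgt <- target_grid

  # cross every target cell with every source cell, keep positive overlaps
  pairs <- tidyr::crossing(
    tcell = tgt$cell_id,
    scell = src$cell_id
  )
  ti <- match(pairs$tcell, tgt$cell_id)
  si <- match(pairs$scell, src$cell_id)
  dlon <- pmin(tgt$lon_e[ti], src$lon_e[si]) - pmax(tgt$lon_w[ti], src$lon_w[si])
  dlat <- pmin(tgt$lat_n[ti], src$lat_n[si]) - pmax(tgt$lat_s[ti], src$lat_s[si])
  area <- pmax(dlon, 0) * pmax(dlat, 0)
  keep <- area > 0 & !is.na(src$value[si])

  agg <- tibble::tibble(
    cell_id = pairs$tcell[keep],
    w = area[keep],
    v = src$value[si[keep]]
  )
  agg <- dplyr::summarise(
    dplyr::group_by(agg, .data$cell_id),
    value = sum(.data$w * .data$v) / sum(.data$w),
    .groups = "drop"
  )
  out <- dplyr::left_join(tibble::tibble(cell_id = tgt$cell_id), agg, by = "cell_id")
  n_missing <- sum(is.na(out$value))
  if (n_missing > 0) {
    warning(n_missing, " target cell(s) have no source overlap and are set to NA",
            call. = FALSE)
  }
  out
}

#' Form an exposure delta from baseline and future fields
#'
#' Pairs a baseline (ca. 2000) and a future (ca. 2050) seasonal-mean MDA8
#' field on the same grid and computes the per-cell change
#' `delta = future - baseline` (ppb). Negative deltas are ozone decreases
#' under climate change and are preserved as such.
#'
#' @param baseline,future Tibbles `cell_id`, `value` on the same grid.
#' @return A tibble of class `o3_delta` with columns `cell_id`, `baseline`,
#'   `future`, `delta`.
#' @export
make_delta <- function(baseline, future) {
  stopifnot(all(c("cell_id", "value") %in% names(baseline)),
            all(c("cell_id", "value") %in% names(future)))
  if (nrow(baseline) != nrow(future) ||
      !setequal(baseline$cell_id, future$cell_id)) {
    stop("baseline and future fields must share the same grid cells", call. = FALSE)
  }
  fut <- future$value[match(baseline$cell_id, future$cell_id)]
  base <- baseline$value
  out <- tibble::tibble(
    cell_id = baseline$cell_id,
    baseline = base,
    future = fut,
    delta = fut - base
  )
  class(out) <- c("o3_delta", class(out))
  out
}
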