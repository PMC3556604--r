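#' Build a rectangular analysis grid
#'
#' Constructs a regular longitude/latitude grid of `nx` by `ny` equal cells
#' covering a bounding box. This is the common analysis grid that all ozone
#' and population fields are expressed on; it stands in for the ~30 km
#' national grid that gridded air-quality output is remapped to.
#'
#' @param nx,ny Number of cells in the longitude and latitude directions.
#' @param bbox Numeric length-4 vector `c(lon_w, lon_e, lat_s, lat_n)` in
#'   degrees. The default spans the conterminous United States.
#' @param nominal_resolution_km Nominal cell size in km, stored as an
#'   attribute for reporting only.
#'
#' @return A tibble of class `o3_grid` with one row per cell and columns
#'   `cell_id`, `lon_w`, `lon_e`, `lat_s`, `lat_n`, `lon`, `lat` (cell
#'   centers, degrees).
#' @examples
#' g <- make_grid(4, 3)
#' assign_regions(g)
#' @export
make_grid <- function(nx, ny, bbox = c(-125, -67, 25, 49),
                      nominal_resolution_km = 30) {
  stopifnot(length(nx) == 1, length(ny) == 1, nx >= 1, ny >= 1)
  if (length(bbox) != 4 || bbox[1] >= bbox[2] || bbox[3] >= bbox[4]) {
    stop("`bbox` must be c(lon_w, lon_e, lat_s, lat_n) with lon_w < lon_e and lat_s < lat_n",
         call. = FALSE)
  }
  lon_edges <- seq(bbox[1], bbox[2], length.out = nx + 1)
  lat_edges <- seq(bbox[3], bbox[4], length.out = ny + 1)
  cells <- tidyr::expand_grid(iy = seq_len(ny), ix = seq_len(nx))
  grid <- tibble::tibble(
    cell_id = seq_len(nx * ny),
    lon_w = lon_edges[cells$ix],
    lon_e = lon_edges[cells$ix + 1],
    lat_s = lat_edges[cells$iy],
    lat_n = lat_edges[cells$iy + 1]
  )
  grid$lon <- (grid$lon_w + grid$lon_e) / 2
  grid$lat <- (grid$lat_s + grid$lat_n) / 2
  attr(grid, "nx") <- as.integer(nx)
  attr(grid, "ny") <- as.integer(ny)
  attr(grid, "nominal_resolution_km") <- nominal_resolution_km
  class(grid) <- c("o3_grid", class(grid))
  validate_grid(grid)
}

#' @keywords internal
validate_grid <- function(grid) {
  req <- c("cell_id", "lon_w", "lon_e", "lat_s", "lat_n", "lon", "lat")
  missing_cols <- setdiff(req, names(grid))
  if (length(missing_cols) > 0) {
    stop("grid is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(grid$cell_id)) stop("grid cell_ids must be unique", call. = FALSE)
  bad <- grid$lon_w >= grid$lon_e | grid$lat_s >= grid$lat_n
  if (any(bad)) {
    stop("degenerate cell bounds for cell_id ",
         paste(utils::head(grid$cell_id[bad], 5), collapse = ", "), call. = FALSE)
  }
  inside <- grid$lon >= grid$lon_w & grid$lon <= grid$lon_e &
    grid$lat >= grid$lat_s & grid$lat <= grid$lat_n
  if (!all(inside)) stop("cell centers must lie inside their bounds", call. = FALSE)
  grid
}

#' Assign grid cells to the three analysis regions
#'
#' Classifies each cell center into Northeast (east of `lon_split` and north
#' of `lat_split`), Southeast (east of `lon_split`, south of `lat_split`) or
#' West (everything west of `lon_split`). The three labels partition the
#' conterminous-US grid. Ties: centers exactly on `lon_split` go West;
#' centers exactly on `lat_split` east of the split go Northeast
#' (north-inclusive reading of "north of").
#'
#' @param grid An `o3_grid` (or any data frame with `cell_id`, `lon`, `lat`).
#' @param lon_split,lat_split Region boundary meridian/parallel, degrees.
#'   Defaults: 100°W and 36.5°N.
#'
#' @return A tibble `cell_id`, `region` with
#'   `region ∈ {"Northeast","Southeast","West"}`.
#' @export
assign_regions <- function(grid, lon_split = -100, lat_split = 36.5) {
  stopifnot(all(c("cell_id", "lon", "lat") %in% names(grid)))
  region <- dplyr::case_when(
    grid$lon <= lon_split ~ "West",
    grid$lat >= lat_split ~ "Northeast",
    TRUE ~ "Southeast"
  )
  tibble::tibble(cell_id = grid$cell_id, region = region)
}

#' Read and write grid definitions and gridded fields as CSV
#'
#' The on-disk interchange formats are long-format CSV: a grid definition
#' (`cell_id,lon_w,lon_e,lat_s,lat_n`) and a field
#' (`cell_id,lon,lat,value`).
#'
#' @param path File path.
#' @param grid,field Objects to write.
#' @return `read_grid()` returns an `o3_grid` tibble; `read_field()` a
#'   tibble `cell_id`, `value`.
#' @name grid-io
NULL

#' @rdname grid-io
#' @export
read_grid <- function(path) {
  g <- readr::read_csv(path, show_col_types = FALSE)
  g$lon <- (g$lon_w + g$lon_e) / 2
  g$lat <- (g$lat_s + g$lat_n) / 2
  class(g) <- c("o3_grid", class(g))
  validate_grid(g)
}

#' @rdname grid-io
#' @export
write_grid <- function(grid, path) {
  readr::write_csv(grid[c("cell_id", "lon_w", "lon_e", "lat_s", "lat_n")], path)
  invisible(path)
}

#' @rdname grid-io
#' @param grid_ref Optional grid supplying `lon`/`lat` columns on write.
#' @export
write_field <- function(field, path, grid_ref = NULL) {
  out <- field
  if (!is.null(grid_ref)) {
    out <- dplyr::left_join(field, grid_ref[c("cell_id", "lon", "lat")], by = "cell_id")
    out <- out[c("cell_id", "lon", "lat", "value")]
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname grid-io
#' @export
read_field <- function(path) {
  f <- readr::read_csv(path, show_col_types = FALSE)
  tibble::as_tibble(f[intersect(c("cell_id", "value"), names(f))])
}
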