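#' IUGG mean Earth radius (km)
#'
#' Fixed constant used for every cell area and haversine distance in the
#' package, so independent oracles can match results bit-for-bit.
#' @export
EARTH_RADIUS_KM <- 6371.0088

#' Define a regular longitude-latitude grid
#'
#' Cells are indexed 0-based, row-major from the northwest corner: cell
#' `id = row * n_col + col`, with the centre of cell `(row, col)` at
#' `(lon_min + (col + 0.5) * resolution, lat_max - (row + 0.5) * resolution)`.
#' Cell labels are `"cell_<id>"`.
#'
#' @param lon_min,lon_max,lat_min,lat_max grid bounds in degrees.
#' @param resolution cell edge in degrees (default 1, the 1-degree grid used
#'   for gridded range maps).
#' @return an object of class `grid_spec`.
#' @examples
#' g <- grid_spec(-10, 10, -10, 10, 1)
#' g$n_cells
#' @export
grid_spec <- function(lon_min = -10, lon_max = 10, lat_min = -10, lat_max = 10,
                      resolution = 1) {
  stopifnot(is.numeric(resolution), length(resolution) == 1L, resolution > 0)
  if (lat_min < -90 || lat_max > 90 || lat_min >= lat_max)
    stop("latitude bounds must satisfy -90 <= lat_min < lat_max <= 90")
  if (lon_min < -180 || lon_max > 180 || lon_min >= lon_max)
    stop("longitude bounds must satisfy -180 <= lon_min < lon_max <= 180")
  n_row <- (lat_max - lat_min) / resolution
  n_col <- (lon_max - lon_min) / resolution
  if (abs(n_row - round(n_row)) > 1e-8 || abs(n_col - round(n_col)) > 1e-8)
    stop("grid bounds must span an integer number of cells at this resolution")
  g <- list(lon_min = lon_min, lon_max = lon_max,
            lat_min = lat_min, lat_max = lat_max,
            resolution = resolution,
            n_row = as.integer(round(n_row)),
            n_col = as.integer(round(n_col)))
  g$n_cells <- g$n_row * g$n_col
  class(g) <- "grid_spec"
  g
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells (%g deg), lon [%g, %g], lat [%g, %g]\n",
              x$n_row, x$n_col, x$resolution,
              x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

#' Cell labels of a grid
#' @param grid a [grid_spec()].
#' @return character vector `"cell_0" ... "cell_<n-1>"` in row-major order.
#' @export
cell_labels <- function(grid) {
  paste0("cell_", seq_len(grid$n_cells) - 1L)
}

#' Cell centres of a grid
#'
#' @param grid a [grid_spec()].
#' @return data frame with columns `cell` (label), `row`, `col` (0-based),
#'   `lon`, `lat` (degrees of the cell centre), in row-major order.
#' @export
cell_centers <- function(grid) {
  idx <- seq_len(grid$n_cells) - 1L
  row <- idx %/% grid$n_col
  col <- idx %% grid$n_col
  data.frame(cell = cell_labels(grid), row = row, col = col,
             lon = grid$lon_min + (col + 0.5) * grid$resolution,
             lat = grid$lat_max - (row + 0.5) * grid$resolution,
             stringsAsFactors = FALSE)
}

#' Spherical area of the cells in one latitude band
#'
#' Area of a `resolution x resolution` cell whose row is `row_index`
#' (0-based from the north edge): `R^2 * dlambda * (sin(phi_top) -
#' sin(phi_bottom))` with `R = EARTH_RADIUS_KM`. All cells in a row share
#' the same area.
#'
#' @param grid a [grid_spec()].
#' @param row_index 0-based row index (vectorised).
#' @return area in km^2.
#' @examples
#' g <- grid_spec(-1, 1, -1, 1, 1)
#' cell_area(g, 0) # ~ 1.236e4 km^2 at the equator
#' @export
cell_area <- function(grid, row_index) {
  stopifnot(all(row_index >= 0), all(row_index < grid$n_row))
  lat_top <- grid$lat_max - row_index * grid$resolution
  lat_bot <- lat_top - grid$resolution
  dlam <- grid$resolution * pi / 180
  EARTH_RADIUS_KM^2 * dlam * (sin(lat_top * pi / 180) - sin(lat_bot * pi / 180))
}

#' Per-cell areas for a whole grid
#' @param grid a [grid_spec()].
#' @return numeric vector, one area (km^2) per cell in row-major order.
#' @export
grid_cell_areas <- function(grid) {
  idx <- seq_len(grid$n_cells) - 1L
  cell_area(grid, idx %/% grid$n_col)
}

validate_pam <- function(pam, grid = NULL) {
  if (!is.matrix(pam)) stop("presence-absence matrix must be a matrix")
  if (is.null(rownames(pam)) || is.null(colnames(pam)))
    stop("presence-absence matrix needs host row names and cell column names")
  if (!all(pam %in% c(0, 1))) stop("presence-absence matrix must be binary")
  if (any(rowSums(pam) < 1))
    stop("every host must occupy at least one cell; empty range for: ",
         paste(rownames(pam)[rowSums(pam) < 1], collapse = ", "))
  if (!is.null(grid) && ncol(pam) != grid$n_cells)
    stop("presence-absence matrix columns do not match the grid cell count")
  invisible(TRUE)
}
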