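# Equal-area reference grid.
#
# Cylindrical equal-area projection on the WGS84 ellipsoid with a chosen
# standard parallel (30 degrees gives the Behrmann projection). Forward
# equations: with k0 = cos(phi_s) / sqrt(1 - e^2 sin^2 phi_s),
#   x = a * lambda * k0,      y = a * q(phi) / (2 * k0),
# where q is the authalic-latitude auxiliary. Column and row counts are the
# projected world width and latitude-band height divided by the cell size and
# rounded to the nearest integer, the convention of the reference raster this
# grid reproduces (96.5 km cells, standard parallel 30, 90N-60S -> 360 x 142
# = 51,120 cells).

.WGS84_A_KM <- 6378.137
.WGS84_E2 <- 0.00669437999014

.cea_q <- function(lat_deg) {
  e2 <- .WGS84_E2
  e <- sqrt(e2)
  s <- sin(lat_deg * pi / 180)
  (1 - e2) * (s / (1 - e2 * s^2) - (1 / (2 * e)) * log((1 - e * s) / (1 + e * s)))
}

.cea_k0 <- function(standard_parallel) {
  phi <- standard_parallel * pi / 180
  cos(phi) / sqrt(1 - .WGS84_E2 * sin(phi)^2)
}

#' Build the equal-area reference grid
#'
#' Constructs a cylindrical equal-area (Behrmann-style) raster grid covering
#' a latitude band. All cells have identical area `cell_size_km^2`; cell ids
#' are row-major integers starting at 1 in the north-west corner.
#'
#' @param cell_size_km Cell edge length in km at the standard parallel.
#' @param standard_parallel Latitude (degrees) of true scale; 30 for the
#'   Behrmann projection.
#' @param lat_max,lat_min Northern and southern extent in degrees
#'   (`lat_min < lat_max`).
#' @return An object of class `equal_area_grid` with fields `n_rows`,
#'   `n_cols`, `n_cells`, `cell_size_km`, the extent, and the projected
#'   frame dimensions (`width_km`, `height_km`, with the origin at the
#'   south-west corner).
#' @examples
#' build_reference_grid() # 360 x 142 = 51,120 cells
#' @export
build_reference_grid <- function(cell_size_km = 96.5, standard_parallel = 30,
                                 lat_max = 90, lat_min = -60) {
  if (cell_size_km <= 0) abort("`cell_size_km` must be positive")
  if (lat_min >= lat_max) abort("`lat_min` must be below `lat_max`")
  k0 <- .cea_k0(standard_parallel)
  width <- 2 * pi * .WGS84_A_KM * k0
  y <- function(lat) .WGS84_A_KM * .cea_q(lat) / (2 * k0)
  height <- y(lat_max) - y(lat_min)
  n_cols <- max(1L, as.integer(round(width / cell_size_km)))
  n_rows <- max(1L, as.integer(round(height / cell_size_km)))
  structure(list(
    cell_size_km = cell_size_km,
    standard_parallel = standard_parallel,
    lat_max = lat_max,
    lat_min = lat_min,
    n_rows = n_rows,
    n_cols = n_cols,
    n_cells = n_rows * n_cols,
    width_km = n_cols * cell_size_km,
    height_km = n_rows * cell_size_km
  ), class = "equal_area_grid")
}

#' Custom equal-area grid with explicit dimensions
#'
#' Builds a grid with given row/column counts instead of deriving them from
#' a latitude band; handy for small synthetic runs. Cells keep the
#' equal-area property (`cell_size_km^2` each).
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param cell_size_km Cell edge length in km.
#' @return An `equal_area_grid`.
#' @export
custom_grid <- function(n_rows, n_cols, cell_size_km = 96.5) {
  if (n_rows < 1 || n_cols < 1 || cell_size_km <= 0) {
    abort("grid dimensions and cell size must be positive")
  }
  structure(list(
    cell_size_km = cell_size_km,
    standard_parallel = NA_real_,
    lat_max = NA_real_,
    lat_min = NA_real_,
    n_rows = as.integer(n_rows),
    n_cols = as.integer(n_cols),
    n_cells = as.integer(n_rows) * as.integer(n_cols),
    width_km = n_cols * cell_size_km,
    height_km = n_rows * cell_size_km
  ), class = "equal_area_grid")
}

#' @export
print.equal_area_grid <- function(x, ...) {
  cat(sprintf(
    "<equal_area_grid> %d rows x %d cols = %d cells of %g km (parallel %g, %g to %g deg lat)\n",
    x$n_rows, x$n_cols, x$n_cells, x$cell_size_km,
    x$standard_parallel, x$lat_min, x$lat_max))
  invisible(x)
}

#' Cell id / row-column conversions
#'
#' Cells are numbered row-major from 1 at the north-west corner; `row` and
#' `col` are 0-based (raster convention, row 0 at the top).
#'
#' @param grid An [build_reference_grid()] grid.
#' @param row,col 0-based row and column indices.
#' @param cell 1-based cell ids.
#' @return `cell_id()` returns cell ids; `cell_rowcol()` a tibble with
#'   `cell`, `row`, `col`.
#' @export
cell_id <- function(grid, row, col) {
  if (any(row < 0 | row >= grid$n_rows | col < 0 | col >= grid$n_cols)) {
    abort("row/col indices fall outside the grid")
  }
  as.integer(row) * grid$n_cols + as.integer(col) + 1L
}

#' @rdname cell_id
#' @export
cell_rowcol <- function(grid, cell) {
  if (any(cell < 1 | cell > grid$n_cells)) abort("cell ids outside the grid")
  cell <- as.integer(cell)
  tibble(cell = cell,
         row = (cell - 1L) %/% grid$n_cols,
         col = (cell - 1L) %% grid$n_cols)
}

#' Projected rectangle of grid cells
#'
#' Returns each cell's bounding rectangle in the grid's projected km frame
#' (origin at the south-west corner, y increasing northwards).
#'
#' @inheritParams cell_rowcol
#' @return Tibble with `cell`, `xmin`, `xmax`, `ymin`, `ymax` (km).
#' @export
cell_rect <- function(grid, cell) {
  rc <- cell_rowcol(grid, cell)
  s <- grid$cell_size_km
  tibble(cell = rc$cell,
         xmin = rc$col * s,
         xmax = (rc$col + 1) * s,
         ymin = (grid$n_rows - 1 - rc$row) * s,
         ymax = (grid$n_rows - rc$row) * s)
}
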