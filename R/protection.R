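# Protected-area records, coverage and hotspot overlay.
#
# Records mirror a simplified WDPA-style layer: a tibble with columns `id`,
# `status`, `designation`, `geometry` (list-column; each element a ring or a
# list of rings in the grid's projected km frame, or NULL for point
# records), `x`, `y` (point coordinates, km) and `reported_area` (km^2, for
# point records).

#' Filter protected-area records
#'
#' Applies the standard inclusion rules: drop records (i) with status
#' "Not Reported" or "Proposed", (ii) designated "UNESCO-MAB Biosphere
#' Reserve", and (iii) provided as points (no geometry) without a reported
#' area. Point records with a reported area are retained (to be buffered).
#' Removal counts per rule are reported; the operation is idempotent.
#'
#' @param records Tibble of protected-area records (see above).
#' @return The filtered tibble (a subset of the input rows).
#' @export
filter_records <- function(records) {
  need <- c("status", "designation")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(sprintf("records lack columns: %s", paste(miss, collapse = ", ")))
  }
  r1 <- records$status %in% c("Not Reported", "Proposed")
  r2 <- records$designation %in% "UNESCO-MAB Biosphere Reserve"
  if ("geometry" %in% names(records)) {
    is_point <- vapply(records$geometry, is.null, logical(1))
  } else {
    is_point <- rep(TRUE, nrow(records))
  }
  area <- if ("reported_area" %in% names(records)) records$reported_area else NA_real_
  r3 <- is_point & (is.na(area) | area <= 0)
  inform(sprintf(
    "excluded %d by status, %d as MAB biosphere reserves, %d unbuffered points",
    sum(r1), sum(r2 & !r1), sum(r3 & !r1 & !r2)))
  records[!(r1 | r2 | r3), , drop = FALSE]
}

#' Buffer a point record into an area-true circle
#'
#' Builds a regular polygon centred on the point whose area equals the
#' reported area exactly (the circumradius is inflated to compensate for the
#' polygon's inscribed-area deficit). Constructed in the equal-area
#' projected plane, the enclosed area equals the reported area on the
#' globe, which is the quantity a geodesic buffer fixes.
#'
#' @param x,y Point coordinates in the projected frame (km).
#' @param reported_area Target area in km^2 (> 0).
#' @param n_vertices Number of polygon vertices (default 64).
#' @return A ring matrix (see [polygon_area()]).
#' @examples
#' polygon_area(buffer_point(0, 0, 100)) # 100
#' @export
buffer_point <- function(x, y, reported_area, n_vertices = 64L) {
  if (!is.numeric(reported_area) || length(reported_area) != 1 ||
      is.na(reported_area) || reported_area <= 0) {
    abort("`reported_area` must be a positive number")
  }
  n <- as.integer(n_vertices)
  r <- sqrt(2 * reported_area / (n * sin(2 * pi / n)))
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(x + r * cos(th), y + r * sin(th))
}

# flatten record geometries (+ buffered points) into a list of rings
.record_rings <- function(records, n_vertices = 64L) {
  rings <- list()
  for (i in seq_len(nrow(records))) {
    g <- if ("geometry" %in% names(records)) records$geometry[[i]] else NULL
    if (is.null(g)) {
      rings <- c(rings, list(buffer_point(records$x[i], records$y[i],
                                          records$reported_area[i],
                                          n_vertices)))
    } else if (is.matrix(g)) {
      rings <- c(rings, list(g))
    } else {
      rings <- c(rings, g)
    }
  }
  rings
}

#' Dissolve polygons into a single protected-area union
#'
#' Merges a set of rings, removing overlaps and redundancy: the dissolved
#' area counts every covered point once. Degenerate rings are repaired where
#' possible (duplicate vertices dropped); an unrepairable ring aborts with
#' the offending record named.
#'
#' @param polygons List of ring matrices (or nested lists of rings); names,
#'   if present, identify records in error messages.
#' @return An object of class `dissolved_area`: the cleaned rings plus the
#'   exact union area (km^2).
#' @examples
#' sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' dissolve(list(sq, sq + 0.5))$area # 1.75
#' @export
dissolve <- function(polygons) {
  if (is.matrix(polygons)) polygons <- list(polygons)
  flat <- list()
  for (i in seq_along(polygons)) {
    g <- polygons[[i]]
    nm <- names(polygons)[i]
    id <- if (!is.null(nm) && nzchar(nm)) nm else as.character(i)
    gl <- if (is.matrix(g)) list(g) else g
    for (ring in gl) flat[[length(flat) + 1]] <- .as_ring(ring, id)
  }
  if (length(flat) == 0) abort("no polygons to dissolve")
  structure(list(rings = flat, area = .union_area_window(flat)),
            class = "dissolved_area")
}

#' @export
print.dissolved_area <- function(x, ...) {
  cat(sprintf("<dissolved_area> %d ring(s), union area %.4g km^2\n",
              length(x$rings), x$area))
  invisible(x)
}

#' Percent of each grid cell covered by a protected-area union
#'
#' Intersects the dissolved protected-area union with every grid cell and
#' reports the covered percentage of the cell surface. Geometries must be in
#' the grid's projected km frame (origin at the south-west corner).
#'
#' @param union A [dissolve()] result, or a list of ring matrices.
#' @param grid An [build_reference_grid()] grid.
#' @return An object of class `coverage_grid`: list with the `grid` and a
#'   `coverage` tibble (`cell`, `coverage` in percent, every cell).
#' @export
coverage_per_cell <- function(union, grid) {
  stopifnot(inherits(grid, "equal_area_grid"))
  rings <- if (inherits(union, "dissolved_area")) union$rings else union
  if (is.matrix(rings)) rings <- list(rings)
  s <- grid$cell_size_km
  cov <- numeric(grid$n_cells)
  # map rings to candidate cells via bounding boxes
  cand <- new.env(parent = emptyenv())
  for (k in seq_along(rings)) {
    p <- rings[[k]]
    c0 <- max(0L, as.integer(floor(min(p[, 1]) / s)))
    c1 <- min(grid$n_cols - 1L, as.integer(ceiling(max(p[, 1]) / s)) - 1L)
    rtop <- max(0L, grid$n_rows - as.integer(ceiling(max(p[, 2]) / s)))
    rbot <- min(grid$n_rows - 1L,
                grid$n_rows - 1L - as.integer(floor(min(p[, 2]) / s)))
    if (c1 < c0 || rbot < rtop) next
    for (r in rtop:rbot) for (cc in c0:c1) {
      key <- as.character(r * grid$n_cols + cc + 1L)
      cand[[key]] <- c(cand[[key]], k)
    }
  }
  for (key in ls(cand)) {
    cell <- as.integer(key)
    rect <- cell_rect(grid, cell)
    a <- .union_area_window(rings[unique(cand[[key]])],
                            rect$xmin, rect$xmax, rect$ymin, rect$ymax)
    cov[cell] <- min(100, max(0, 100 * a / s^2))
  }
  structure(list(grid = grid,
                 coverage = tibble(cell = seq_len(grid$n_cells),
                                   coverage = cov)),
            class = "coverage_grid")
}

#' Coverage grid from per-cell values
#'
#' Wraps an existing per-cell percent-protected field (e.g. read from a
#' file or simulated) as a `coverage_grid`.
#'
#' @param grid An [build_reference_grid()] grid.
#' @param coverage Numeric vector of length `n_cells` (percent, 0-100), or a
#'   tibble with columns `cell` and `coverage`.
#' @return A `coverage_grid`.
#' @export
coverage_grid <- function(grid, coverage) {
  stopifnot(inherits(grid, "equal_area_grid"))
  if (is.data.frame(coverage)) {
    v <- numeric(grid$n_cells)
    if (any(coverage$cell < 1 | coverage$cell > grid$n_cells)) {
      abort("coverage cell ids outside the grid")
    }
    v[coverage$cell] <- coverage$coverage
    coverage <- v
  }
  if (length(coverage) != grid$n_cells) {
    abort("`coverage` length must equal the grid cell count")
  }
  if (any(coverage < 0 | coverage > 100, na.rm = TRUE)) {
    abort("coverage values must lie in [0, 100]")
  }
  structure(list(grid = grid,
                 coverage = tibble(cell = seq_len(grid$n_cells),
                                   coverage = as.numeric(coverage))),
            class = "coverage_grid")
}

#' @export
print.coverage_grid <- function(x, ...) {
  cat(sprintf("<coverage_grid> %d cells, mean coverage %.2f%%\n",
              nrow(x$coverage), mean(x$coverage$coverage)))
  invisible(x)
}

#' Protection overlay of a hotspot set
#'
#' Summarises how well a set of hotspot cells (e.g. the priority areas) is
#' covered by protected areas: the overall protected percentage of their
#' total surface (equal-area cells make the unweighted mean area-true), the
#' number of cells with no protection at all, the number at or above the
#' heavy-protection threshold, and a three-way per-cell classification
#' (not / slightly / heavily protected).
#'
#' @param coverage A `coverage_grid` (or a tibble with `cell`, `coverage`).
#' @param hotspot_cells Integer cell ids (non-empty, within the grid).
#' @param heavy_threshold Percent coverage from which a cell counts as
#'   heavily protected (default 50).
#' @return An object of class `overlay_summary`: `overall_pct`, `n_not`,
#'   `n_slightly`, `n_heavily`, and the per-cell `classification` tibble.
#' @export
overlay_summary <- function(coverage, hotspot_cells, heavy_threshold = 50) {
  cov <- if (inherits(coverage, "coverage_grid")) coverage$coverage else coverage
  if (length(hotspot_cells) == 0) abort("`hotspot_cells` is empty")
  idx <- match(hotspot_cells, cov$cell)
  if (anyNA(idx)) abort("hotspot cells outside the coverage grid")
  v <- cov$coverage[idx]
  cls <- ifelse(v == 0, "not",
                ifelse(v >= heavy_threshold, "heavily", "slightly"))
  structure(list(
    overall_pct = mean(v),
    n_not = sum(cls == "not"),
    n_slightly = sum(cls == "slightly"),
    n_heavily = sum(cls == "heavily"),
    heavy_threshold = heavy_threshold,
    classification = tibble(cell = hotspot_cells, coverage = v,
                            protection_class = factor(cls, levels = c(
                              "not", "slightly", "heavily")))
  ), class = "overlay_summary")
}

#' @export
print.overlay_summary <- function(x, ...) {
  cat(sprintf(
    "<overlay_summary> %d cells: %.1f%% of surface protected; %d not, %d slightly, %d heavily (>=%g%%) protected\n",
    nrow(x$classification), x$overall_pct, x$n_not, x$n_slightly,
    x$n_heavily, x$heavy_threshold))
  invisible(x)
}
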