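#' Assemble a presence/absence matrix on the reference grid
#'
#' Builds the sparse cells x species occurrence matrix from long-format
#' occurrence records. Records may address cells either by 0-based
#' `row`/`col` (raster convention, row 0 at the top) or by 1-based row-major
#' `cell` id. Duplicate records collapse to a single presence. Species listed
#' in `species` but absent from the records are retained with empty ranges
#' (and reported).
#'
#' @param grid An [build_reference_grid()] grid.
#' @param occurrences Data frame with column `species` plus either
#'   `row` and `col` or `cell`.
#' @param species Optional character vector fixing the full species set and
#'   column order; defaults to the species present in `occurrences`.
#' @return An object of class `presence_matrix`: list with the `grid`, the
#'   `species` labels and the sparse logical matrix `mat` (cells x species).
#' @export
assemble_presence <- function(grid, occurrences, species = NULL) {
  stopifnot(inherits(grid, "equal_area_grid"))
  if (!"species" %in% names(occurrences)) {
    abort("`occurrences` needs a `species` column")
  }
  if (all(c("row", "col") %in% names(occurrences))) {
    cells <- cell_id(grid, occurrences$row, occurrences$col)
  } else if ("cell" %in% names(occurrences)) {
    cells <- occurrences$cell
    if (any(cells < 1 | cells > grid$n_cells)) {
      abort(sprintf("cell ids outside the %d-cell grid (grid mismatch?)",
                    grid$n_cells))
    }
    cells <- as.integer(cells)
  } else {
    abort("`occurrences` needs either `row`+`col` or `cell` columns")
  }
  species <- species %||% sort(unique(as.character(occurrences$species)))
  if (anyDuplicated(species)) abort("`species` labels must be unique")
  j <- match(as.character(occurrences$species), species)
  if (anyNA(j)) {
    abort(sprintf("occurrence records for species outside the species list: %s",
                  paste(utils::head(unique(occurrences$species[is.na(j)]), 5),
                        collapse = ", ")))
  }
  keep <- !duplicated(cbind(cells, j))
  mat <- Matrix::sparseMatrix(i = cells[keep], j = j[keep],
                              dims = c(grid$n_cells, length(species)))
  empty <- species[Matrix::colSums(mat) == 0]
  if (length(empty) > 0) {
    inform(sprintf("%d species with zero occupied cells retained: %s",
                   length(empty),
                   paste(utils::head(empty, 5), collapse = ", ")))
  }
  structure(list(grid = grid, species = species, mat = mat),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("<presence_matrix> %d cells x %d species, %d presences\n",
              nrow(x$mat), ncol(x$mat), Matrix::nnzero(x$mat)))
  invisible(x)
}

#' Per-species range sizes
#'
#' Occupied-cell counts (the column sums of the presence matrix); the range
#' size drives rarity weighting and DD imputation.
#'
#' @param pm A [assemble_presence()] presence matrix.
#' @return Tibble with `species` and integer `range_size`.
#' @export
range_sizes <- function(pm) {
  stopifnot(inherits(pm, "presence_matrix"))
  rs <- Matrix::colSums(pm$mat)
  if (any(rs == 0)) {
    warn(sprintf("%d species occupy zero cells", sum(rs == 0)))
  }
  tibble(species = pm$species, range_size = as.integer(rs))
}
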