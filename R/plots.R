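# ggplot2 views of the result objects.

#' Map a cell score on the reference grid
#'
#' Raster map of one per-cell score in grid row/column space, optionally
#' outlining a hotspot set.
#'
#' @param scores Cell-score tibble (`cell` + score columns).
#' @param grid The [build_reference_grid()] grid the cells refer to.
#' @param score Score column to map (default: second column).
#' @param hotspot_cells Optional cell ids to outline.
#' @return A ggplot object.
#' @export
plot_cell_map <- function(scores, grid, score = NULL, hotspot_cells = NULL) {
  score <- score %||% names(scores)[2]
  dat <- dplyr::bind_cols(cell_rowcol(grid, scores$cell),
                          value = scores[[score]])
  gg <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$col, y = -.data$row,
                                          fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = score, x = NULL, y = NULL,
                  title = sprintf("%s on the %d x %d reference grid",
                                  score, grid$n_rows, grid$n_cols)) +
    ggplot2::theme_minimal()
  if (!is.null(hotspot_cells) && length(hotspot_cells) > 0) {
    hs <- cell_rowcol(grid, hotspot_cells)
    gg <- gg + ggplot2::geom_tile(
      data = hs, ggplot2::aes(x = .data$col, y = -.data$row),
      inherit.aes = FALSE, fill = NA, colour = "red", linewidth = 0.2)
  }
  gg
}

#' @describeIn run_species_analysis Scatter of two species scores coloured
#'   by Red List category.
#' @param object A `species_analysis`.
#' @param x_score,y_score Score columns to plot.
#' @export
autoplot.species_analysis <- function(object, x_score = "HEDGE",
                                      y_score = "LEDGE", ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data[[x_score]], y = .data[[y_score]],
                               colour = .data$category)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(title = sprintf("%s vs %s (medians over %d trees)",
                                  x_score, y_score, object$meta$n_trees)) +
    ggplot2::theme_minimal()
}

#' @describeIn run_spatial_analysis Map of one cell score with its hotspots
#'   outlined.
#' @param object A `spatial_analysis`.
#' @param score Cell score to map (default `"GexpPD"`).
#' @export
autoplot.spatial_analysis <- function(object, score = "GexpPD", ...) {
  plot_cell_map(object$cell_scores, object$meta$grid, score = score,
                hotspot_cells = object$hotspots[[score]])
}

#' @describeIn run_protection_analysis Stacked protection-class counts per
#'   hotspot set.
#' @param object A `protection_analysis`.
#' @export
autoplot.protection_analysis <- function(object, ...) {
  dat <- tidyr::pivot_longer(
    object$table,
    cols = c("n_not", "n_slightly", "n_heavily"),
    names_to = "class", names_prefix = "n_", values_to = "n")
  dat$class <- factor(dat$class, levels = c("not", "slightly", "heavily"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$score, y = .data$n,
                                    fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "hotspot cells", fill = "protection") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
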