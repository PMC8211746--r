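# broom-style tidiers for the analysis result objects.

#' @describeIn run_species_analysis Tidy per-species score table.
#' @param x A `species_analysis`.
#' @param ... Unused.
#' @export
tidy.species_analysis <- function(x, ...) {
  x$scores
}

#' @describeIn run_species_analysis One-row summary: sizes and the headline
#'   score correlations.
#' @export
glance.species_analysis <- function(x, ...) {
  rho <- function(a, b) {
    r <- x$correlations
    r$rho[(r$score_a == a & r$score_b == b) | (r$score_a == b & r$score_b == a)]
  }
  ov <- function(a, b) {
    r <- x$top_overlaps
    r$overlap_pct[(r$set_a == a & r$set_b == b) | (r$set_a == b & r$set_b == a)]
  }
  tibble(
    n_species = x$meta$n_species,
    n_trees = x$meta$n_trees,
    top_fraction = x$meta$top_fraction,
    top_set_size = length(x$top_sets$HEDGE),
    rho_HEDGE_EDGE = rho("EDGE", "HEDGE"),
    rho_HEDGE_LEDGE = rho("HEDGE", "LEDGE"),
    overlap_HEDGE_EDGE_pct = ov("EDGE", "HEDGE"),
    overlap_HEDGE_LEDGE_pct = ov("HEDGE", "LEDGE")
  )
}

#' @describeIn run_spatial_analysis Tidy cell-score table (scores joined
#'   with the proportion maps).
#' @param x A `spatial_analysis`.
#' @param ... Unused.
#' @export
tidy.spatial_analysis <- function(x, ...) {
  left_join(x$cell_scores, x$proportions, by = "cell")
}

#' @describeIn run_spatial_analysis One-row summary: dimensions, hotspot
#'   size and the GexpPD/LexpPD hotspot overlap.
#' @export
glance.spatial_analysis <- function(x, ...) {
  r <- x$hotspot_overlaps
  gl <- r$overlap_pct[(r$set_a == "GexpPD" & r$set_b == "LexpPD") |
                        (r$set_a == "LexpPD" & r$set_b == "GexpPD")]
  rr <- x$correlations
  rho_gl <- rr$rho[(rr$score_a == "GexpPD" & rr$score_b == "LexpPD") |
                     (rr$score_a == "LexpPD" & rr$score_b == "GexpPD")]
  tibble(
    n_cells = x$meta$n_cells,
    n_species = x$meta$n_species,
    n_trees = x$meta$n_trees,
    hotspot_fraction = x$meta$hotspot_fraction,
    hotspot_size = x$meta$hotspot_size,
    rho_GexpPD_LexpPD = rho_gl,
    overlap_GexpPD_LexpPD_pct = gl
  )
}

#' @describeIn run_protection_analysis Tidy per-hotspot-set summary table.
#' @param x A `protection_analysis`.
#' @param ... Unused.
#' @export
tidy.protection_analysis <- function(x, ...) {
  x$table
}

#' @describeIn run_protection_analysis One-row summary across hotspot sets.
#' @export
glance.protection_analysis <- function(x, ...) {
  tibble(
    n_sets = nrow(x$table),
    heavy_threshold = x$meta$heavy_threshold,
    min_overall_pct = min(x$table$overall_pct),
    max_overall_pct = max(x$table$overall_pct)
  )
}
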