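# Orchestration of the three analyses: species scores, cell scores,
# protection overlay, plus the cross-run comparison workflow.

.SCORE_NAMES <- c("ED", "EDGE", "HEDGE", "LEDGE")

.pairwise_spearman <- function(tab, cols, id = names(tab)[1]) {
  pairs <- utils::combn(cols, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    ok <- !is.na(tab[[a]]) & !is.na(tab[[b]])
    tibble(score_a = a, score_b = b,
           rho = cor(tab[[a]][ok], tab[[b]][ok], method = "spearman"))
  })
}

.pairwise_overlap <- function(sets) {
  pairs <- utils::combn(names(sets), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    tibble(set_a = a, set_b = b,
           overlap_pct = set_overlap(sets[[a]], sets[[b]]))
  })
}

#' Species-level prioritization analysis
#'
#' Runs the full species workflow over a tree ensemble: imputes any DD
#' statuses from range size, converts categories to extinction
#' probabilities, computes per-tree ED / HEDGE / LEDGE and takes per-species
#' medians across trees, applies the EDGE transform to the median ED,
#' ranks every score (rank 1 = highest), flags the top-fraction sets, and
#' reports pairwise Spearman correlations and top-set overlaps between the
#' four scores.
#'
#' @param ensemble A [tree_ensemble()].
#' @param risk Risk table (`species`, `category`, `range_size`); DD rows are
#'   imputed internally.
#' @param model An [extinction_model()].
#' @param top_fraction Fraction defining the top sets (default 0.25).
#' @return An object of class `species_analysis` with elements `scores`
#'   (per-species tibble), `correlations`, `top_sets` (named list),
#'   `top_overlaps`, and `meta`.
#' @export
run_species_analysis <- function(ensemble, risk, model = extinction_model(),
                                 top_fraction = 0.25) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  leaves <- ensemble_leaves(ensemble)
  miss <- setdiff(leaves, risk$species)
  if (length(miss) > 0) {
    abort(sprintf("risk table lacks tree species: %s",
                  paste(utils::head(miss, 5), collapse = ", ")))
  }
  risk <- impute_dd(risk)
  risk <- assign_extinction_probabilities(risk, model)
  p <- setNames(risk$p_ext, risk$species)

  ed <- median_over_trees(ensemble, evolutionary_distinctiveness)
  hed <- median_over_trees(ensemble, hedge_scores, p = p)
  led <- median_over_trees(ensemble, ledge_scores, p = p)

  scores <- ed |>
    left_join(hed, by = "species") |>
    left_join(led, by = "species") |>
    left_join(select(risk, "species", "category", "p_ext"), by = "species") |>
    mutate(EDGE = edge_score(.data$ED, ge_weight(.data$category))) |>
    select("species", "category", "p_ext", "ED", "EDGE", "HEDGE", "LEDGE")

  for (sc in .SCORE_NAMES) {
    rk <- order(order(-scores[[sc]], scores$species))
    scores[[paste0("rank_", sc)]] <- rk
  }
  top_sets <- lapply(setNames(.SCORE_NAMES, .SCORE_NAMES), function(sc) {
    top_fraction(select(scores, "species", dplyr::all_of(sc)), top_fraction)
  })
  for (sc in .SCORE_NAMES) {
    scores[[paste0("top_", sc)]] <- scores$species %in% top_sets[[sc]]
  }

  structure(list(
    scores = scores,
    correlations = .pairwise_spearman(scores, .SCORE_NAMES),
    top_sets = top_sets,
    top_overlaps = .pairwise_overlap(top_sets),
    meta = list(n_species = nrow(scores), n_trees = length(ensemble),
                top_fraction = top_fraction, model = model)
  ), class = "species_analysis")
}

#' @export
print.species_analysis <- function(x, ...) {
  cat(sprintf("<species_analysis> %d species, %d tree(s), top fraction %g (%d species per set)\n",
              x$meta$n_species, x$meta$n_trees, x$meta$top_fraction,
              length(x$top_sets$HEDGE)))
  print(x$correlations)
  invisible(x)
}

.CELL_SCORES <- c("SR", "TSR", "RSR", "SWR", "PD", "TPD", "RPD", "PWR",
                  "top_HEDGE_SR", "top_LEDGE_SR", "GexpPD", "LexpPD")

#' Cell-level prioritization analysis
#'
#' Computes the twelve per-cell scores on the reference grid (species
#' richness, threatened and rare richness, species-weighted rarity; PD,
#' threatened and rare PD, phylogenetic endemism; richness in the top HEDGE
#' and top LEDGE species; GexpPD and LexpPD), the eight proportion maps,
#' the hotspot set of every score, and pairwise score correlations and
#' hotspot overlaps. Phylogeny-based scores are medians over the ensemble.
#'
#' @param pm A [assemble_presence()] presence matrix.
#' @param ensemble A [tree_ensemble()] covering the matrix's species.
#' @param risk Risk table; DD rows imputed internally.
#' @param model An [extinction_model()].
#' @param species An optional `species_analysis` from
#'   [run_species_analysis()] supplying the top HEDGE/LEDGE sets; computed
#'   internally when omitted.
#' @param hotspot_fraction Hotspot percentile fraction (default 0.025).
#' @return An object of class `spatial_analysis` with `cell_scores`,
#'   `proportions`, `hotspots` (named list of cell-id vectors),
#'   `correlations`, `hotspot_overlaps`, and `meta`.
#' @export
run_spatial_analysis <- function(pm, ensemble, risk,
                                 model = extinction_model(),
                                 species = NULL,
                                 hotspot_fraction = 0.025) {
  stopifnot(inherits(pm, "presence_matrix"), inherits(ensemble, "tree_ensemble"))
  if (Matrix::nnzero(pm$mat) == 0) {
    abort("presence matrix is empty: no occurrences to analyse")
  }
  if (is.null(species)) {
    species <- run_species_analysis(ensemble, risk, model)
  }
  risk <- impute_dd(risk)
  risk <- assign_extinction_probabilities(risk, model)
  p <- setNames(risk$p_ext, risk$species)

  sp_scores <- species_cell_scores(pm, risk)
  pd3 <- median_over_trees(ensemble, function(tr) pd_cell_scores(pm, tr, risk))
  pwr <- median_over_trees(ensemble, function(tr) phylogenetic_endemism(pm, tr))
  gx <- median_over_trees(ensemble, function(tr) gexp_pd(pm, tr, p))
  lx <- median_over_trees(ensemble, function(tr) lexp_pd(pm, tr, p))
  th <- top_set_richness(pm, intersect(species$top_sets$HEDGE, pm$species),
                         name = "top_HEDGE_SR")
  tl <- top_set_richness(pm, intersect(species$top_sets$LEDGE, pm$species),
                         name = "top_LEDGE_SR")

  cell_scores <- sp_scores |>
    left_join(pd3, by = "cell") |>
    left_join(pwr, by = "cell") |>
    left_join(th, by = "cell") |>
    left_join(tl, by = "cell") |>
    left_join(gx, by = "cell") |>
    left_join(lx, by = "cell")

  prop <- tibble(cell = cell_scores$cell)
  ratio <- function(num, den) ifelse(cell_scores[[den]] == 0, NA_real_,
                                     cell_scores[[num]] / cell_scores[[den]])
  prop$prop_TSR <- ratio("TSR", "SR")
  prop$prop_RSR <- ratio("RSR", "SR")
  prop$mean_SWR <- ratio("SWR", "SR")
  prop$prop_TPD <- ratio("TPD", "PD")
  prop$prop_RPD <- ratio("RPD", "PD")
  prop$mean_PWR <- ratio("PWR", "PD")
  prop$prop_top_HEDGE <- ratio("top_HEDGE_SR", "SR")
  prop$prop_top_LEDGE <- ratio("top_LEDGE_SR", "SR")

  hs <- lapply(setNames(.CELL_SCORES, .CELL_SCORES), function(sc) {
    hotspots(cell_scores, fraction = hotspot_fraction, score = sc)
  })

  structure(list(
    cell_scores = cell_scores,
    proportions = prop,
    hotspots = hs,
    correlations = .pairwise_spearman(cell_scores, .CELL_SCORES),
    hotspot_overlaps = .pairwise_overlap(hs),
    meta = list(n_cells = pm$grid$n_cells, n_species = length(pm$species),
                n_trees = length(ensemble),
                hotspot_fraction = hotspot_fraction,
                hotspot_size = length(hs[[1]]), grid = pm$grid)
  ), class = "spatial_analysis")
}

#' @export
print.spatial_analysis <- function(x, ...) {
  cat(sprintf("<spatial_analysis> %d cells x %d species, %d tree(s); hotspots of %d cells (fraction %g)\n",
              x$meta$n_cells, x$meta$n_species, x$meta$n_trees,
              x$meta$hotspot_size, x$meta$hotspot_fraction))
  invisible(x)
}

#' Protection overlay analysis
#'
#' Overlays a protection-coverage grid with the hotspot sets of a spatial
#' analysis (or any named list of cell sets) and summarises each: overall
#' protected percentage, unprotected and heavily protected cell counts, and
#' the per-cell classification.
#'
#' @param coverage A `coverage_grid`.
#' @param hotspot_sets Named list of hotspot cell-id vectors, or a
#'   `spatial_analysis` (its `GexpPD` and `LexpPD` hotspots are then the
#'   priority and loss-significant areas).
#' @param heavy_threshold Heavy-protection threshold in percent.
#' @return An object of class `protection_analysis` with `summaries` (named
#'   list of [overlay_summary()] objects) and a tidy `table`.
#' @export
run_protection_analysis <- function(coverage, hotspot_sets,
                                    heavy_threshold = 50) {
  if (inherits(hotspot_sets, "spatial_analysis")) {
    hotspot_sets <- hotspot_sets$hotspots
  }
  if (is.null(names(hotspot_sets)) || any(!nzchar(names(hotspot_sets)))) {
    abort("`hotspot_sets` must be a named list of cell sets")
  }
  summaries <- lapply(hotspot_sets, function(cells) {
    overlay_summary(coverage, cells, heavy_threshold)
  })
  table <- purrr::map_dfr(names(summaries), function(nm) {
    s <- summaries[[nm]]
    tibble(score = nm, n_cells = nrow(s$classification),
           overall_pct = s$overall_pct, n_not = s$n_not,
           n_slightly = s$n_slightly, n_heavily = s$n_heavily)
  })
  structure(list(summaries = summaries, table = table,
                 meta = list(heavy_threshold = heavy_threshold)),
            class = "protection_analysis")
}

#' @export
print.protection_analysis <- function(x, ...) {
  cat(sprintf("<protection_analysis> %d hotspot set(s), heavy threshold %g%%\n",
              nrow(x$table), x$meta$heavy_threshold))
  print(x$table)
  invisible(x)
}

#' Compare two species-analysis runs
#'
#' Per-score Spearman correlation and top-set overlap between two runs
#' (e.g. the same pipeline on two alternative phylogenies). Runs over
#' different species sets are aligned on the intersection with a warning;
#' top sets are then recomputed on the aligned tables.
#'
#' @param run_a,run_b `species_analysis` objects.
#' @return Tibble with one row per score: `score`, `rho`,
#'   `top_overlap_pct`; the species coverage of the alignment is attached
#'   as attribute `coverage`.
#' @export
compare_runs <- function(run_a, run_b) {
  stopifnot(inherits(run_a, "species_analysis"),
            inherits(run_b, "species_analysis"))
  sa <- run_a$scores; sb <- run_b$scores
  common <- intersect(sa$species, sb$species)
  if (length(common) == 0) abort("runs share no species")
  coverage <- length(common) / length(union(sa$species, sb$species))
  if (coverage < 1) {
    warn(sprintf("runs aligned on %d shared species (%.0f%% coverage)",
                 length(common), 100 * coverage))
  }
  sa <- sa[match(common, sa$species), ]
  sb <- sb[match(common, sb$species), ]
  frac <- run_a$meta$top_fraction
  out <- purrr::map_dfr(.SCORE_NAMES, function(sc) {
    ta <- top_fraction(tibble(species = sa$species, v = sa[[sc]]), frac)
    tb <- top_fraction(tibble(species = sb$species, v = sb[[sc]]), frac)
    tibble(score = sc,
           rho = cor(sa[[sc]], sb[[sc]], method = "spearman"),
           top_overlap_pct = set_overlap(ta, tb))
  })
  attr(out, "coverage") <- coverage
  out
}
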