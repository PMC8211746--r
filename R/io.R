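# Plain-text interchange: CSV tables with provenance headers, species
# tables, presence triplets, coverage fields, and YAML run configurations.

#' Write a table as CSV with provenance header lines
#'
#' Prepends `#`-prefixed provenance comments (config hash, seed, tree
#' count, ...) so every output records how it was produced; the payload is
#' standard CSV. Output is byte-stable: identical inputs give identical
#' files.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param provenance Named list of scalar provenance fields.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path, provenance = list()) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (nm in names(provenance)) {
    writeLines(sprintf("# %s: %s", nm, format(provenance[[nm]])), con)
  }
  write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-headed CSV table
#'
#' @param path CSV path written by [write_table_csv()] (plain CSV also
#'   works).
#' @return A tibble; provenance lines are attached as attribute
#'   `provenance`.
#' @export
read_table_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  prov <- grep("^#", lines, value = TRUE)
  out <- as_tibble(read.csv(text = lines[!grepl("^#", lines)]))
  attr(out, "provenance") <- sub("^# ", "", prov)
  out
}

#' Read a species risk table from CSV
#'
#' Expects columns `species`, `category` and (optionally) `range_size`.
#'
#' @param path CSV path.
#' @return A validated risk tibble.
#' @export
read_species_table <- function(path) {
  x <- read_table_csv(path)
  need <- c("species", "category")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("species table lacks columns: %s",
                  paste(miss, collapse = ", ")))
  }
  if (!"range_size" %in% names(x)) x$range_size <- NA_real_
  species_risk_table(x$species, x$category, x$range_size)
}

#' Read presence triplets from CSV
#'
#' Long-format occurrences with columns `species` plus `row`,`col`
#' (0-based) or `cell` (1-based row-major).
#'
#' @param path CSV path.
#' @param grid Reference grid the records must conform to.
#' @param species Optional full species list (zero-range species retained).
#' @return A [assemble_presence()] presence matrix.
#' @export
read_presence <- function(path, grid, species = NULL) {
  assemble_presence(grid, read_table_csv(path), species = species)
}

#' Read a per-cell coverage field from CSV
#'
#' Columns `cell` and `coverage` (percent).
#'
#' @param path CSV path.
#' @param grid Reference grid.
#' @return A `coverage_grid`.
#' @export
read_coverage <- function(path, grid) {
  x <- read_table_csv(path)
  if (!all(c("cell", "coverage") %in% names(x))) {
    abort("coverage table needs columns `cell` and `coverage`")
  }
  coverage_grid(grid, x)
}

#' Read a run configuration from YAML
#'
#' Fills defaults for the analysis constants (top fraction 0.25, hotspot
#' fraction 0.025, the default extinction model) and validates ranges.
#' Recognised keys: `seed`, `trees`, `species_table`, `presence`,
#' `coverage`, `out_dir`, `top_fraction`, `hotspot_fraction`,
#' `heavy_threshold`, `n_trees`, `grid` (cell_size_km, standard_parallel,
#' lat_max, lat_min), `extinction_model` (horizon_years, prob_by_category),
#' `synth` (arguments of [synth_config()]).
#'
#' @param path YAML file path.
#' @return A named list (class `run_config`) with defaults applied.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config not found: %s", path))
  cfg <- yaml::read_yaml(path)
  cfg$top_fraction <- cfg$top_fraction %||% 0.25
  cfg$hotspot_fraction <- cfg$hotspot_fraction %||% 0.025
  cfg$heavy_threshold <- cfg$heavy_threshold %||% 50
  cfg$seed <- cfg$seed %||% 1
  if (cfg$top_fraction <= 0 || cfg$top_fraction > 1 ||
      cfg$hotspot_fraction <= 0 || cfg$hotspot_fraction >= 1) {
    abort("fractions out of range in run config")
  }
  g <- cfg$grid %||% list()
  cfg$grid <- build_reference_grid(
    cell_size_km = g$cell_size_km %||% 96.5,
    standard_parallel = g$standard_parallel %||% 30,
    lat_max = g$lat_max %||% 90,
    lat_min = g$lat_min %||% -60
  )
  m <- cfg$extinction_model %||% list()
  cfg$extinction_model <- extinction_model(
    prob_by_category = unlist(m$prob_by_category) %||%
      formals(extinction_model)$prob_by_category |> eval(),
    horizon_years = m$horizon_years %||% 50
  )
  structure(cfg, class = "run_config")
}

#' Provenance fields for output tables
#'
#' @param cfg A run config (or any list); hashed into a stable id.
#' @param ... Additional scalar fields (e.g. `n_trees`).
#' @return Named list suitable for [write_table_csv()].
#' @export
provenance_fields <- function(cfg, ...) {
  c(list(config_hash = rlang::hash(cfg[order(names(cfg))]),
         seed = cfg$seed %||% NA), list(...))
}
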