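#' Red List vocabulary
#'
#' The closed category vocabulary used throughout: least concern (LC), near
#' threatened (NT), vulnerable (VU), endangered (EN), critically endangered
#' (CR) and data deficient (DD). Extinct / extinct-in-the-wild categories are
#' out of vocabulary (only extant species are analysed) and are rejected on
#' input. DD must be imputed (see [impute_dd()]) before any scoring.
#'
#' @format Character vector of the six categories.
#' @export
red_list_categories <- c("LC", "NT", "VU", "EN", "CR", "DD")

.check_categories <- function(category, allow_dd = FALSE) {
  bad <- setdiff(unique(category), red_list_categories)
  if (length(bad) > 0) {
    abort(sprintf("unknown Red List category: %s (extinct categories are not accepted)",
                  paste(bad, collapse = ", ")))
  }
  if (!allow_dd && any(category == "DD")) {
    abort("data-deficient (DD) categories must be imputed first; see `impute_dd()`")
  }
  invisible(category)
}

#' Global endangerment (GE) weight of a Red List category
#'
#' LC = 0, NT = 1, VU = 2, EN = 3, CR = 4; the weight entering the EDGE
#' score.
#'
#' @param category Character vector of categories (no DD).
#' @return Integer vector of weights in 0..4.
#' @examples
#' ge_weight(c("LC", "CR"))
#' @export
ge_weight <- function(category) {
  .check_categories(category)
  w <- c(LC = 0L, NT = 1L, VU = 2L, EN = 3L, CR = 4L)
  unname(w[category])
}

#' Is a category threatened?
#'
#' Threatened means vulnerable, endangered or critically endangered.
#'
#' @inheritParams ge_weight
#' @return Logical vector.
#' @export
is_threatened <- function(category) {
  .check_categories(category)
  category %in% c("VU", "EN", "CR")
}

#' Extinction-probability model over a time horizon
#'
#' Maps non-DD Red List categories to probabilities of extinction within a
#' horizon. The default is the widely used 50-year projection of Red List
#' categories ("IUCN50"): LC 0.00005, NT 0.004, VU 0.05, EN 0.42, CR 0.97.
#' The mapping is an editable argument, not a constant: every expected-PD
#' statistic is conditional on this model.
#'
#' @param prob_by_category Named numeric vector over LC, NT, VU, EN, CR with
#'   strictly increasing probabilities in `[0, 1]`.
#' @param horizon_years Time horizon the probabilities refer to (years).
#' @return An object of class `extinction_model`.
#' @examples
#' extinction_model()
#' @export
extinction_model <- function(prob_by_category = c(LC = 0.00005, NT = 0.004,
                                                  VU = 0.05, EN = 0.42,
                                                  CR = 0.97),
                             horizon_years = 50) {
  need <- c("LC", "NT", "VU", "EN", "CR")
  if (!all(need %in% names(prob_by_category))) {
    abort("`prob_by_category` must name all of LC, NT, VU, EN, CR")
  }
  p <- prob_by_category[need]
  if (any(p < 0 | p > 1)) abort("probabilities must lie in [0, 1]")
  if (any(diff(p) <= 0)) {
    abort("probabilities must be strictly increasing from LC to CR")
  }
  structure(list(prob_by_category = p, horizon_years = horizon_years),
            class = "extinction_model")
}

#' @export
print.extinction_model <- function(x, ...) {
  cat(sprintf("<extinction_model> horizon %s years\n", x$horizon_years))
  print(x$prob_by_category)
  invisible(x)
}

#' Extinction probability of a category under a model
#'
#' @inheritParams ge_weight
#' @param model An [extinction_model()].
#' @return Numeric vector of probabilities.
#' @export
extinction_probability <- function(category, model = extinction_model()) {
  stopifnot(inherits(model, "extinction_model"))
  .check_categories(category)
  unname(model$prob_by_category[category])
}

#' Species risk table
#'
#' Builds the per-species table of Red List category and range size (occupied
#' grid-cell count) used by the scoring pipeline.
#'
#' @param species Character vector of unique labels.
#' @param category Red List categories (DD allowed; impute before scoring).
#' @param range_size Non-negative occupied-cell counts.
#' @return A tibble with columns `species`, `category`, `range_size`.
#' @export
species_risk_table <- function(species, category, range_size) {
  if (anyDuplicated(species)) abort("species labels must be unique")
  .check_categories(category, allow_dd = TRUE)
  if (length(category) != length(species) ||
      length(range_size) != length(species)) {
    abort("`species`, `category` and `range_size` must have equal length")
  }
  if (any(range_size < 0)) abort("`range_size` must be >= 0")
  tibble(species = as.character(species),
         category = as.character(category),
         range_size = as.numeric(range_size))
}

#' Attach extinction probabilities to a risk table
#'
#' @param table A risk table (see [species_risk_table()]) without DD rows.
#' @param model An [extinction_model()].
#' @return The table with a `p_ext` column added (or replaced).
#' @export
assign_extinction_probabilities <- function(table, model = extinction_model()) {
  .check_categories(table$category)
  mutate(table, p_ext = extinction_probability(.data$category, model))
}

#' Impute data-deficient categories from range size
#'
#' Replaces every DD row by a concrete category using a range-size
#' quantile-bracket rule calibrated on the non-DD species: categories are
#' ordered by increasing typical range (CR < EN < VU < NT < LC, reflecting
#' the small ranges of highly threatened species), brackets on the
#' range-size quantile scale are sized by the category shares among non-DD
#' species, and each DD species is assigned the bracket its own range-size
#' quantile falls into. The rule is a documented approximation standing in
#' for richer status-imputation models; it is monotone (smaller range, more
#' threatened imputation) and idempotent.
#'
#' @param table A risk table with columns `species`, `category`,
#'   `range_size`.
#' @return The table with no DD rows; non-DD rows unchanged; an `imputed`
#'   logical column marks replaced rows. With no DD rows the input is
#'   returned untouched.
#' @export
impute_dd <- function(table) {
  .check_categories(table$category, allow_dd = TRUE)
  is_dd <- table$category == "DD"
  if (!any(is_dd)) return(table)
  known <- table[!is_dd, , drop = FALSE]
  if (nrow(known) == 0) {
    abort("cannot impute: every species is DD (no calibration data)")
  }
  if (anyNA(table$range_size[is_dd])) {
    abort("DD species must have a known range size for imputation")
  }
  ordering <- c("CR", "EN", "VU", "NT", "LC")
  present <- ordering[ordering %in% known$category]
  shares <- table(factor(known$category, levels = present)) / nrow(known)
  breaks <- cumsum(as.numeric(shares))
  q <- ecdf(known$range_size)(table$range_size[is_dd])
  # first bracket whose cumulative share reaches the species' quantile
  idx <- findInterval(q, breaks, left.open = TRUE) + 1L
  idx <- pmin(idx, length(present))
  out <- table
  out$category[is_dd] <- present[idx]
  out$imputed <- is_dd
  out
}
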