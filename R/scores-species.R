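# Expected-PD engine and per-species scores.
#
# All scores are sums over branches of the rooted tree. For a branch b with
# length l_b and descendant leaves L(b), and per-species extinction
# probabilities p over a fixed horizon:
#
#   expected PD      = sum_b l_b * (1 - prod_{i in L(b)} p_i)
#   HEDGE_i (gain)   = sum_{b : i in L(b)} l_b * prod_{j in L(b)} p_j
#   LEDGE_i (loss)   = sum_{b : i in L(b)} l_b * (1 - p_i) * prod_{j != i} p_j
#   ED_i   (fair     = sum_{b : i in L(b)} l_b / |L(b)|
#           proportion)
#
# HEDGE/LEDGE are contractually equal to the two-evaluation definitions
# (expected PD with p_i forced to 0 resp. 1, minus/versus the baseline); the
# per-branch forms above are the fast path and are property-tested against
# the two-evaluation oracle.

# Match a probability specification to the tree leaves. `p` is a named
# numeric vector or a data frame with columns species + p_ext (or value).
.p_vector <- function(p, tip_labels) {
  if (is.data.frame(p)) {
    vcol <- intersect(c("p_ext", "p", "value"), names(p))[1]
    if (is.na(vcol) || !("species" %in% names(p))) {
      abort("`p` data frames need columns `species` and `p_ext`")
    }
    p <- setNames(p[[vcol]], p$species)
  }
  if (is.null(names(p))) abort("`p` must be named by species")
  miss <- setdiff(tip_labels, names(p))
  if (length(miss) > 0) {
    abort(sprintf("no extinction probability for: %s",
                  paste(utils::head(miss, 5), collapse = ", ")))
  }
  pv <- unname(p[tip_labels])
  if (anyNA(pv) || any(pv < 0 | pv > 1)) {
    abort("extinction probabilities must lie in [0, 1]")
  }
  pv
}

#' Expected phylogenetic diversity under extinction probabilities
#'
#' The PD expected to survive to the model's time horizon: each branch
#' survives with probability one minus the product of the extinction
#' probabilities of its descendant species.
#'
#' @param tree A rooted `phylo` tree with branch lengths (Ma).
#' @param p Per-species extinction probabilities: a named numeric vector or a
#'   data frame with columns `species` and `p_ext`. All leaves must be
#'   covered.
#' @return Expected PD in Ma, between 0 and the total tree length.
#' @examples
#' t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' expected_pd(t3, c(A = 0.5, B = 0.5, C = 0.5)) # 2.75
#' @export
expected_pd <- function(tree, p) {
  bi <- .branch_index(tree)
  pv <- .p_vector(p, bi$tip_labels)
  prodp <- vapply(bi$tips, function(ix) prod(pv[ix]), numeric(1))
  sum(bi$edge_len * (1 - prodp))
}

#' HEDGE: gain in expected PD from securing one species
#'
#' For each species, the increase in expected PD if its extinction
#' probability were brought to 0 while all other probabilities stay fixed.
#' Species that are already safe (`p = 0`) score 0; highly threatened,
#' evolutionarily distinctive species score highest.
#'
#' @inheritParams expected_pd
#' @return A tibble with columns `species` and `HEDGE` (Ma).
#' @export
hedge_scores <- function(tree, p) {
  bi <- .branch_index(tree)
  pv <- .p_vector(p, bi$tip_labels)
  out <- numeric(bi$n_tips)
  for (b in seq_along(bi$tips)) {
    ix <- bi$tips[[b]]
    w <- bi$edge_len[b] * prod(pv[ix])
    out[ix] <- out[ix] + w
  }
  tibble(species = bi$tip_labels, HEDGE = out)
}

#' LEDGE: loss in expected PD from losing one species
#'
#' For each species, the drop in expected PD if its extinction probability
#' were raised to 1 while all other probabilities stay fixed. Secure,
#' evolutionarily distinctive species score highest; a species already
#' certain to go extinct (`p = 1`) scores 0.
#'
#' @inheritParams expected_pd
#' @return A tibble with columns `species` and `LEDGE` (Ma).
#' @export
ledge_scores <- function(tree, p) {
  bi <- .branch_index(tree)
  pv <- .p_vector(p, bi$tip_labels)
  out <- numeric(bi$n_tips)
  for (b in seq_along(bi$tips)) {
    ix <- bi$tips[[b]]
    pb <- pv[ix]
    zero <- pb == 0
    nz <- sum(zero)
    if (nz == 0) {
      excl <- prod(pb) / pb
    } else if (nz == 1) {
      excl <- ifelse(zero, prod(pb[!zero]), 0)
    } else {
      excl <- rep(0, length(ix))
    }
    out[ix] <- out[ix] + bi$edge_len[b] * (1 - pb) * excl
  }
  tibble(species = bi$tip_labels, LEDGE = out)
}

#' Fair-proportion evolutionary distinctiveness
#'
#' Each branch's length is shared equally among its descendant species;
#' summing a species' shares along its root path gives its ED. ED partitions
#' PD: the species EDs always sum to the total tree length.
#'
#' @param tree A rooted `phylo` tree with branch lengths (Ma).
#' @return A tibble with columns `species` and `ED` (Ma).
#' @export
evolutionary_distinctiveness <- function(tree) {
  bi <- .branch_index(tree)
  out <- numeric(bi$n_tips)
  for (b in seq_along(bi$tips)) {
    ix <- bi$tips[[b]]
    out[ix] <- out[ix] + bi$edge_len[b] / length(ix)
  }
  tibble(species = bi$tip_labels, ED = out)
}

#' EDGE score
#'
#' `EDGE = ln(1 + ED) + GE * ln(2)`, combining evolutionary distinctiveness
#' with the global endangerment weight (see [ge_weight()]).
#'
#' @param ed Non-negative ED values (Ma).
#' @param ge Integer GE weights in 0..4.
#' @return Dimensionless EDGE scores.
#' @examples
#' edge_score(1.5, 2) # log(2.5) + 2 * log(2)
#' @export
edge_score <- function(ed, ge) {
  if (any(ed < 0)) abort("`ed` must be >= 0")
  if (any(!ge %in% 0:4)) abort("`ge` must be integers in 0..4")
  log1p(ed) + ge * log(2)
}

#' Median score across a tree ensemble
#'
#' Applies a per-tree scorer to every tree of an ensemble and returns the
#' per-item median of each score column, which is how multi-tree
#' phylogenetic uncertainty is absorbed throughout the pipeline. The even-
#' count median is the mean of the two central values.
#'
#' @param ensemble A [tree_ensemble()].
#' @param score_fn Function of `(tree, ...)` returning a data frame whose
#'   first column identifies the item (e.g. `species` or `cell`) and whose
#'   remaining columns are numeric scores.
#' @param ... Passed on to `score_fn`.
#' @return A tibble with the id column and the median of every score column,
#'   sorted by id.
#' @export
median_over_trees <- function(ensemble, score_fn, ...) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  tabs <- purrr::map(unclass(ensemble), score_fn, ...)
  id <- names(tabs[[1]])[1]
  ids0 <- sort(tabs[[1]][[id]])
  for (i in seq_along(tabs)) {
    if (!identical(sort(tabs[[i]][[id]]), ids0)) {
      abort(sprintf("tree %d scored a different `%s` set", i, id))
    }
  }
  bind_rows(tabs) |>
    group_by(.data[[id]]) |>
    summarise(across(dplyr::everything(), median), .groups = "drop") |>
    arrange(.data[[id]])
}

#' Top-scoring fraction of a score table
#'
#' Returns the `floor(fraction * n)` items with the highest score. Ties are
#' broken deterministically (score descending, then label ascending), so the
#' returned set always has exactly `floor(fraction * n)` members even when
#' the cut falls inside a tie block.
#'
#' @param scores A data frame whose first column identifies items and which
#'   contains the score column.
#' @param fraction Proportion in `(0, 1]` (0.25 selects the top quarter).
#' @param score Name of the score column; defaults to the second column.
#' @return Character (or integer) vector of the selected item ids.
#' @examples
#' tb <- tibble::tibble(species = letters[1:8], s = 8:1)
#' top_fraction(tb, 0.25)
#' @export
top_fraction <- function(scores, fraction, score = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    abort("`fraction` must lie in (0, 1]")
  }
  if (nrow(scores) == 0) abort("`scores` is empty")
  score <- score %||% names(scores)[2]
  v <- scores[[score]]
  id <- scores[[1]]
  k <- floor(fraction * nrow(scores))
  ord <- order(-v, id)
  id[ord][seq_len(k)]
}

#' Spearman rank correlation between two score tables
#'
#' Mid-rank handling of ties; the two tables must cover the same item set.
#'
#' @param a,b Data frames whose first column identifies items and second
#'   column holds the score (or name columns via `score_a`/`score_b`).
#' @param score_a,score_b Score column names (default: second column).
#' @return Spearman's rho in `[-1, 1]`.
#' @export
rank_correlation <- function(a, b, score_a = NULL, score_b = NULL) {
  ia <- a[[1]]; ib <- b[[1]]
  if (!setequal(ia, ib) || length(ia) != length(ib)) {
    abort("`a` and `b` must cover the same item set")
  }
  score_a <- score_a %||% names(a)[2]
  score_b <- score_b %||% names(b)[2]
  va <- a[[score_a]]
  vb <- b[[score_b]][match(ia, ib)]
  cor(va, vb, method = "spearman")
}

#' Percentage overlap between two equal-size sets
#'
#' `100 * |a intersect b| / |a|`, the statistic used to compare top-score
#' sets (species or hotspot cells) between scores or between runs.
#'
#' @param a,b Vectors of item ids with `|a| = |b| > 0`.
#' @return Percentage in `[0, 100]`.
#' @export
set_overlap <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("sets must be non-empty")
  if (length(unique(a)) != length(unique(b))) {
    abort("`a` and `b` must have equal sizes")
  }
  100 * length(intersect(a, b)) / length(unique(a))
}
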