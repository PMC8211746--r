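# Per-cell scores on the reference grid.
#
# The phylogeny-based cell scores all reduce to sparse linear algebra on the
# branch x cell intersection pattern M[b, c] = 1 iff branch b has at least
# one descendant species present in cell c:
#   PD(c)     = sum_b l_b M[b, c]
#   PWR(c)    = sum_b (l_b / range_b) M[b, c],  range_b = #cells with M = 1
#   GexpPD(c) = sum_b l_b (prod_{j in L(b)} p_j) M[b, c]
#   LexpPD(c) = sum_b l_b (prod_{j in L(b)\C} p_j - prod_{j in L(b)} p_j)
# where C is the species set of the cell. Zero probabilities are handled
# exactly by tracking zero counts separately from log-products.

.check_pm_risk <- function(pm, risk) {
  miss <- setdiff(pm$species, risk$species)
  if (length(miss) > 0) {
    abort(sprintf("species missing from the risk table: %s",
                  paste(utils::head(miss, 5), collapse = ", ")))
  }
  risk[match(pm$species, risk$species), , drop = FALSE]
}

.check_pm_tree <- function(pm, bi) {
  miss <- setdiff(pm$species, bi$tip_labels)
  if (length(miss) > 0) {
    abort(sprintf("species absent from the tree: %s",
                  paste(utils::head(miss, 5), collapse = ", ")))
  }
}

# branch x cell intersection pattern (lgCMatrix) for a species subset
.branch_cell <- function(bi, pm, subset = NULL) {
  B <- .branch_incidence(bi, pm$species)
  mat <- pm$mat
  if (!is.null(subset)) {
    B <- B[, subset, drop = FALSE]
    mat <- mat[, subset, drop = FALSE]
  }
  M <- B %*% Matrix::t(mat)      # counts of shared species
  M > 0
}

#' Species-based cell scores: SR, TSR, RSR, SWR
#'
#' Per grid cell: species richness (SR), threatened species richness (TSR:
#' VU/EN/CR), rare species richness (RSR: species whose range size is
#' strictly below the median range size over all species), and
#' species-weighted rarity (SWR: the sum over present species of the inverse
#' of their range size, also known as weighted endemism).
#'
#' @param pm A [assemble_presence()] presence matrix.
#' @param risk Risk table covering every species of `pm`, with no DD rows.
#' @return Tibble with `cell`, `SR`, `TSR`, `RSR`, `SWR` for every grid
#'   cell (empty cells score 0).
#' @export
species_cell_scores <- function(pm, risk) {
  stopifnot(inherits(pm, "presence_matrix"))
  risk <- .check_pm_risk(pm, risk)
  .check_categories(risk$category)
  rs <- Matrix::colSums(pm$mat)
  med <- median(rs)
  thr <- is_threatened(risk$category)
  rare <- rs < med
  w <- ifelse(rs > 0, 1 / rs, 0)
  tibble(
    cell = seq_len(pm$grid$n_cells),
    SR = as.integer(Matrix::rowSums(pm$mat)),
    TSR = as.integer(Matrix::rowSums(pm$mat[, thr, drop = FALSE])),
    RSR = as.integer(Matrix::rowSums(pm$mat[, rare, drop = FALSE])),
    SWR = as.numeric(pm$mat %*% w)
  )
}

#' Phylogeny-based cell scores: PD, TPD, RPD
#'
#' Per grid cell: Faith's PD of the present species (rooted convention, see
#' [total_pd()]), threatened PD (PD of the present threatened species only)
#' and rare PD (PD of the present rare species only, rarity as in
#' [species_cell_scores()]). Cells with no qualifying species score 0.
#'
#' @inheritParams species_cell_scores
#' @param tree A rooted `phylo` tree containing every species of `pm`.
#' @return Tibble with `cell`, `PD`, `TPD`, `RPD` (Ma).
#' @export
pd_cell_scores <- function(pm, tree, risk) {
  stopifnot(inherits(pm, "presence_matrix"))
  bi <- .branch_index(tree)
  .check_pm_tree(pm, bi)
  risk <- .check_pm_risk(pm, risk)
  .check_categories(risk$category)
  rs <- Matrix::colSums(pm$mat)
  thr <- is_threatened(risk$category)
  rare <- rs < median(rs)
  pd_of <- function(subset) {
    M <- .branch_cell(bi, pm, subset)
    as.numeric(Matrix::t(M) %*% bi$edge_len)
  }
  tibble(
    cell = seq_len(pm$grid$n_cells),
    PD = pd_of(NULL),
    TPD = pd_of(thr),
    RPD = pd_of(rare)
  )
}

#' Phylogenetic endemism (phylogenetic-weighted rarity, PWR)
#'
#' Per grid cell, the sum over branches with at least one descendant present
#' of the branch length divided by the number of cells where the branch
#' occurs. PWR concentrates spatially restricted PD: summed over all cells
#' it returns the total PD of the branches that occur anywhere.
#'
#' @inheritParams pd_cell_scores
#' @return Tibble with `cell` and `PWR` (Ma).
#' @export
phylogenetic_endemism <- function(pm, tree) {
  stopifnot(inherits(pm, "presence_matrix"))
  bi <- .branch_index(tree)
  .check_pm_tree(pm, bi)
  M <- .branch_cell(bi, pm)
  rng <- Matrix::rowSums(M)
  if (any(rng == 0)) {
    warn(sprintf("%d branches have no occurring descendant and are excluded",
                 sum(rng == 0)))
  }
  w <- ifelse(rng > 0, bi$edge_len / rng, 0)
  tibble(cell = seq_len(pm$grid$n_cells),
         PWR = as.numeric(Matrix::t(M) %*% w))
}

#' Richness of a top-score species set per cell
#'
#' Counts how many members of a top-fraction set (e.g. the TOP 25% HEDGE
#' species) are present in each cell.
#'
#' @inheritParams species_cell_scores
#' @param top_set Character vector of species labels, a subset of the
#'   presence matrix's species.
#' @param name Column name for the count.
#' @return Tibble with `cell` and the count column.
#' @export
top_set_richness <- function(pm, top_set, name = "top_richness") {
  stopifnot(inherits(pm, "presence_matrix"))
  bad <- setdiff(top_set, pm$species)
  if (length(bad) > 0) {
    abort(sprintf("unknown species in `top_set`: %s",
                  paste(utils::head(bad, 5), collapse = ", ")))
  }
  sel <- pm$species %in% top_set
  out <- tibble(cell = seq_len(pm$grid$n_cells),
                count = as.integer(Matrix::rowSums(pm$mat[, sel, drop = FALSE])))
  names(out)[2] <- name
  out
}

#' Cell-level gain in expected PD (GexpPD)
#'
#' For each grid cell, the gain in global expected PD if every species
#' present in the cell were secured (their extinction probabilities forced
#' to 0, all other species unchanged). This is the best-case outcome of
#' perfect local conservation; a cell holding a single species reduces to
#' that species' HEDGE score.
#'
#' @inheritParams pd_cell_scores
#' @inheritParams expected_pd
#' @return Tibble with `cell` and `GexpPD` (Ma), 0 for empty cells.
#' @export
gexp_pd <- function(pm, tree, p) {
  stopifnot(inherits(pm, "presence_matrix"))
  bi <- .branch_index(tree)
  .check_pm_tree(pm, bi)
  pv <- .p_vector(p, bi$tip_labels)
  prodp <- vapply(bi$tips, function(ix) prod(pv[ix]), numeric(1))
  M <- .branch_cell(bi, pm)
  tibble(cell = seq_len(pm$grid$n_cells),
         GexpPD = as.numeric(Matrix::t(M) %*% (bi$edge_len * prodp)))
}

#' Cell-level loss in expected PD (LexpPD)
#'
#' For each grid cell, the loss in global expected PD if every species
#' present in the cell went extinct (their extinction probabilities forced
#' to 1, all other species unchanged). This is the worst-case outcome of a
#' local threat; a cell holding a single species reduces to that species'
#' LEDGE score.
#'
#' @inheritParams gexp_pd
#' @return Tibble with `cell` and `LexpPD` (Ma), 0 for empty cells.
#' @export
lexp_pd <- function(pm, tree, p) {
  stopifnot(inherits(pm, "presence_matrix"))
  bi <- .branch_index(tree)
  .check_pm_tree(pm, bi)
  pv <- .p_vector(p, bi$tip_labels)
  spi <- match(bi$tip_labels, pm$species)  # tree leaf -> pm column
  ok <- !is.na(spi)
  # per-branch log-product over non-zero p and zero count
  lp_branch <- vapply(bi$tips, function(ix) {
    pb <- pv[ix]
    sum(log(pb[pb > 0]))
  }, numeric(1))
  z_branch <- vapply(bi$tips, function(ix) sum(pv[ix] == 0), numeric(1))
  full <- ifelse(z_branch > 0, 0, exp(lp_branch))
  # species-weight incidence matrices with columns in pm$species order
  B <- .branch_incidence(bi, pm$species)
  colp <- numeric(length(pm$species))
  colp[spi[ok]] <- pv[ok]
  Blog <- B %*% Matrix::Diagonal(x = ifelse(colp > 0, log(colp), 0))
  Bzero <- B %*% Matrix::Diagonal(x = as.numeric(colp == 0))
  M <- .branch_cell(bi, pm)
  trip <- Matrix::which(M, arr.ind = TRUE)
  if (nrow(trip) == 0) {
    return(tibble(cell = seq_len(pm$grid$n_cells),
                  LexpPD = numeric(pm$grid$n_cells)))
  }
  Alog <- Blog %*% Matrix::t(pm$mat)   # sum of log p over branch-cell overlap
  Azero <- Bzero %*% Matrix::t(pm$mat) # zero-p species in branch-cell overlap
  lpC <- Alog[trip]
  zC <- Azero[trip]
  b <- trip[, 1]
  excl <- ifelse(z_branch[b] - zC > 0, 0, exp(lp_branch[b] - lpC))
  term <- bi$edge_len[b] * (excl - full[b])
  out <- numeric(pm$grid$n_cells)
  agg <- rowsum(term, group = trip[, 2])
  out[as.integer(rownames(agg))] <- agg[, 1]
  tibble(cell = seq_len(pm$grid$n_cells), LexpPD = out)
}

#' Element-wise proportion of two cell-score tables
#'
#' Ratios such as TSR/SR or TPD/PD. Cells where the denominator is 0 are
#' undefined and flagged as `NA` (masked), never coerced to 0.
#'
#' @param numerator,denominator Cell-score tibbles over the same cells, score
#'   in the second column (or named via `score_num`/`score_den`).
#' @param score_num,score_den Score column names.
#' @param name Output column name.
#' @return Tibble with `cell` and the proportion column.
#' @export
proportion_map <- function(numerator, denominator, score_num = NULL,
                           score_den = NULL, name = "proportion") {
  if (!identical(numerator$cell, denominator$cell)) {
    abort("cell sets differ between numerator and denominator (grid mismatch)")
  }
  score_num <- score_num %||% names(numerator)[2]
  score_den <- score_den %||% names(denominator)[2]
  num <- numerator[[score_num]]
  den <- denominator[[score_den]]
  out <- tibble(cell = numerator$cell,
                value = ifelse(den == 0, NA_real_, num / den))
  names(out)[2] <- name
  out
}

#' Hotspot cells of a score
#'
#' The `floor(fraction * n_defined)` cells with the highest values, the
#' standard 2.5% hotspot rule. Undefined (`NA`, masked) cells never enter
#' the ranking. Ties are broken deterministically (value descending, cell id
#' ascending); a tie crossing the cut boundary triggers a warning.
#'
#' @param scores Cell-score tibble (`cell` + score column).
#' @param fraction Proportion in `(0, 1)`; default 0.025.
#' @param score Score column name (default: second column).
#' @return Integer vector of hotspot cell ids.
#' @export
hotspots <- function(scores, fraction = 0.025, score = NULL) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie in (0, 1)")
  }
  score <- score %||% names(scores)[2]
  v <- scores[[score]]
  cells <- scores$cell
  def <- !is.na(v)
  if (!any(def)) abort("all cells are undefined for this score")
  v <- v[def]; cells <- cells[def]
  k <- floor(fraction * length(v))
  ord <- order(-v, cells)
  if (k > 0 && k < length(v) && v[ord][k] == v[ord][k + 1]) {
    warn("ties at the hotspot boundary; resolved by ascending cell id")
  }
  cells[ord][seq_len(k)]
}
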