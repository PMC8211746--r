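#' Tree ensembles
#'
#' A tree ensemble is an ordered list of rooted [ape::phylo] trees sharing one
#' leaf set, typically samples from a dated posterior distribution of
#' phylogenies. Branch lengths are interpreted in millions of years (Ma)
#' throughout the package, and every phylogenetic score is reported in that
#' unit.
#'
#' @param trees A list of `phylo` objects (or a `multiPhylo`).
#' @return An object of class `tree_ensemble`: a list of `phylo` trees with a
#'   `leaves` attribute holding the shared, sorted leaf labels.
#' @examples
#' t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' ens <- tree_ensemble(list(t3, t3))
#' length(ens)
#' @export
tree_ensemble <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  if (length(trees) < 1) abort("an ensemble needs at least one tree")
  for (i in seq_along(trees)) {
    if (!inherits(trees[[i]], "phylo")) {
      abort(sprintf("tree %d is not a 'phylo' object", i))
    }
    if (is.null(trees[[i]]$edge.length)) {
      abort(sprintf("tree %d has no branch lengths", i))
    }
    if (anyDuplicated(trees[[i]]$tip.label)) {
      abort(sprintf("tree %d has duplicated leaf labels", i))
    }
  }
  ref <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)[-1]) {
    cur <- sort(trees[[i]]$tip.label)
    if (!identical(cur, ref)) {
      extra <- setdiff(cur, ref)
      miss <- setdiff(ref, cur)
      abort(c(
        sprintf("tree %d does not share the leaf set of tree 1", i),
        "*" = sprintf("only in tree %d: %s", i,
                      paste(utils::head(extra, 5), collapse = ", ")),
        "*" = sprintf("only in tree 1: %s",
                      paste(utils::head(miss, 5), collapse = ", "))
      ))
    }
  }
  structure(trees, leaves = ref, class = "tree_ensemble")
}

#' @export
print.tree_ensemble <- function(x, ...) {
  cat(sprintf("<tree_ensemble> %d tree(s) over %d shared leaves\n",
              length(x), length(attr(x, "leaves"))))
  invisible(x)
}

#' @export
`[.tree_ensemble` <- function(x, i) {
  tree_ensemble(unclass(x)[i])
}

#' Leaf labels shared by an ensemble
#' @param ensemble A [tree_ensemble()].
#' @return Sorted character vector of leaf labels.
#' @export
ensemble_leaves <- function(ensemble) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  attr(ensemble, "leaves")
}

#' Read an ensemble of rooted trees
#'
#' Reads a posterior sample of rooted, dated trees from a file, either in
#' one-tree-per-line Newick or in a NEXUS `TREES` block (detected from the
#' `#NEXUS` header). All trees must carry branch lengths and share one leaf
#' set.
#'
#' @param path Path to a Newick or NEXUS tree file.
#' @return A [tree_ensemble()].
#' @examples
#' f <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", f)
#' read_newick(f)
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  txt <- readLines(path, warn = FALSE)
  nonblank <- trimws(txt[nzchar(trimws(txt))])
  if (length(nonblank) == 0) abort(sprintf("file is empty: %s", path))
  if (toupper(substr(nonblank[1], 1, 6)) == "#NEXUS") {
    trees <- ape::read.nexus(path)
    if (inherits(trees, "phylo")) trees <- list(trees)
    if (inherits(trees, "multiPhylo")) trees <- ape::.uncompressTipLabel(trees)
    return(tree_ensemble(trees))
  }
  trees <- vector("list", length(nonblank))
  for (i in seq_along(nonblank)) {
    tr <- tryCatch(
      suppressWarnings(ape::read.tree(text = nonblank[i])),
      error = function(e) NULL
    )
    if (is.null(tr) || !inherits(tr, "phylo")) {
      abort(sprintf("malformed Newick for tree %d in %s", i, path))
    }
    trees[[i]] <- tr
  }
  tree_ensemble(trees)
}

#' Sample trees from an ensemble without replacement
#'
#' Reproducibly draws `k` trees, emulating the extraction of a working sample
#' (e.g. 100 trees) from a larger posterior (e.g. 1000 trees).
#'
#' @param ensemble A [tree_ensemble()].
#' @param k Number of trees to draw (`1 <= k <= length(ensemble)`).
#' @param seed Integer seed making the draw reproducible.
#' @return A [tree_ensemble()] of `k` trees.
#' @export
sample_trees <- function(ensemble, k, seed) {
  stopifnot(inherits(ensemble, "tree_ensemble"))
  n <- length(ensemble)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > n) {
    abort(sprintf("`k` must be between 1 and the ensemble size (%d)", n))
  }
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  idx <- sample.int(n, size = as.integer(k), replace = FALSE)
  ensemble[idx]
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Internal branch index: for every edge of the rooted tree, its length and the
# integer indices of its descendant leaves. Edges are taken in postorder of
# the reordered tree; a root edge, if any, is not represented in ape's edge
# matrix and is therefore ignored (rooted-PD convention).
.branch_index <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be a 'phylo' object")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  nb <- nrow(edge)
  tips <- vector("list", nb)
  node_tips <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(nb)) {
    child <- edge[i, 2L]
    tt <- if (child <= ntip) child else node_tips[[child]]
    tips[[i]] <- sort(tt)
    parent <- edge[i, 1L]
    node_tips[[parent]] <- c(node_tips[[parent]], tt)
  }
  list(
    edge_len = tr$edge.length,
    tips = tips,
    tip_labels = tr$tip.label,
    n_tips = ntip
  )
}

# Sparse branch x species incidence matrix for a branch index, with columns
# ordered as `species`. Tree leaves absent from `species` are dropped from
# the incidence (they cannot intersect any cell of a presence matrix over
# `species`).
.branch_incidence <- function(bi, species = bi$tip_labels) {
  col <- match(bi$tip_labels, species)
  i <- rep.int(seq_along(bi$tips), lengths(bi$tips))
  j <- col[unlist(bi$tips, use.names = FALSE)]
  keep <- !is.na(j)
  Matrix::sparseMatrix(i = i[keep], j = j[keep],
                       dims = c(length(bi$tips), length(species)))
}

#' Branch-to-leaf index of a phylogeny
#'
#' Maps every branch of a rooted tree to the set of leaves descending from it.
#' Pendant branches map to singletons, and the sets form a laminar family
#' (any two are disjoint or nested). This index underlies every
#' sum-over-branches score in the package.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @return A tibble with one row per branch: `branch` (integer id in
#'   postorder), `length` (Ma), `n_leaves`, and `leaves` (list-column of leaf
#'   labels).
#' @examples
#' t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' branch_leaf_index(t3)
#' @export
branch_leaf_index <- function(tree) {
  bi <- .branch_index(tree)
  tibble(
    branch = seq_along(bi$tips),
    length = bi$edge_len,
    n_leaves = lengths(bi$tips),
    leaves = lapply(bi$tips, function(ix) bi$tip_labels[ix])
  )
}

#' Faith's phylogenetic diversity of a leaf subset
#'
#' Sum of branch lengths of the minimal subtree connecting `subset` to the
#' root of the full tree (rooted convention: the path to the root is
#' included, so a single species scores its full root-path length and the
#' complete leaf set scores the total tree length).
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param subset Character vector of leaf labels (may be empty).
#' @return PD in Ma (0 for the empty set).
#' @examples
#' t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' total_pd(t3, c("A", "B", "C")) # 5
#' total_pd(t3, "A")              # 2
#' @export
total_pd <- function(tree, subset) {
  bi <- .branch_index(tree)
  if (length(subset) == 0) return(0)
  idx <- match(subset, bi$tip_labels)
  if (anyNA(idx)) {
    abort(sprintf("unknown species: %s",
                  paste(subset[is.na(idx)], collapse = ", ")))
  }
  inset <- logical(bi$n_tips)
  inset[idx] <- TRUE
  keep <- vapply(bi$tips, function(ix) any(inset[ix]), logical(1))
  sum(bi$edge_len[keep])
}
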