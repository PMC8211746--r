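# Shared fixtures and independent oracles.

# the worked three-species tree: ((A:1,B:1):1,C:2)
t3 <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
p_half <- c(A = 0.5, B = 0.5, C = 0.5)

# random rooted binary tree with uniform branch lengths
random_tree <- function(n) ape::rtree(n)

# random probability vector over a tree's leaves, occasionally pinning
# coordinates to exactly 0 or 1 to exercise the degenerate branches
random_p <- function(tree, pin = TRUE) {
  n <- length(tree$tip.label)
  p <- stats::runif(n)
  if (pin && n > 2) {
    k <- sample(0:2, 1)
    if (k > 0) p[sample(n, k)] <- sample(c(0, 1), k, replace = TRUE)
  }
  stats::setNames(p, tree$tip.label)
}

# Independent rooted-PD oracle: union of root-path edges via ape::nodepath,
# never touching the package's branch indexing.
pd_path_oracle <- function(tree, subset) {
  if (length(subset) == 0) return(0)
  root <- length(tree$tip.label) + 1L
  key <- paste(tree$edge[, 1], tree$edge[, 2])
  used <- unique(unlist(lapply(match(subset, tree$tip.label), function(tip) {
    np <- ape::nodepath(tree, from = root, to = tip)
    paste(np[-length(np)], np[-1])
  })))
  sum(tree$edge.length[key %in% used])
}

# Brute-force expected PD: enumerate all survival outcomes (n <= ~10)
expected_pd_enum <- function(tree, p) {
  labs <- tree$tip.label
  n <- length(labs)
  p <- p[labs]
  total <- 0
  for (m in 0:(2^n - 1)) {
    surv <- bitwAnd(m, 2^(seq_len(n) - 1)) > 0
    pr <- prod(ifelse(surv, 1 - p, p))
    if (pr > 0) total <- total + pr * pd_path_oracle(tree, labs[surv])
  }
  total
}

# tiny grid + presence matrix from a named list species -> cell ids
make_pm <- function(grid, occupancy, species = names(occupancy)) {
  occ <- dplyr::bind_rows(lapply(names(occupancy), function(sp) {
    tibble::tibble(species = sp, cell = occupancy[[sp]])
  }))
  suppressMessages(pdgain::assemble_presence(grid, occ, species = species))
}

# random presence matrix over a tree's leaves on a small grid
random_pm <- function(tree, n_cells = 4) {
  grid <- pdgain::custom_grid(1, n_cells, 100)
  labs <- tree$tip.label
  occ <- lapply(labs, function(sp) {
    sort(sample(n_cells, sample(0:n_cells, 1)))
  })
  names(occ) <- labs
  occ <- occ[lengths(occ) > 0]
  if (length(occ) == 0) occ <- stats::setNames(list(1L), labs[1])
  make_pm(grid, occ, species = labs)
}

unit_square <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))

shift_ring <- function(ring, dx = 0, dy = 0) {
  cbind(ring[, 1] + dx, ring[, 2] + dy)
}
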