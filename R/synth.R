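# Seeded generators of synthetic study inputs.
#
# The generators emulate the statistical shape of the real inputs the
# pipeline consumes -- a posterior sample of dated ultrametric phylogenies, a
# Red List status profile with a data-deficient fraction, spatially
# contiguous gridded ranges with a heavy-tailed size distribution, and a
# patchy per-cell protection field -- without any biogeographic realism. All
# are pure functions of (config, seed): each generator derives its stream
# from the config seed plus a fixed per-generator offset, so outputs are
# byte-identical across runs and the generators can be called in any order.

#' Configuration of the synthetic-data generators
#'
#' Defaults describe the desk-scale study conditions used throughout the
#' package's tests: 1000 species; a Red List profile with roughly a quarter
#' of assessed species threatened and a 14.2% data-deficient fraction
#' (mirroring the mammal Red List); pure-birth trees with speciation rate
#' 0.05 / Ma (root depths of the order of 100 Ma for 1000 species);
#' log-normal range sizes with median 10 cells and log-sd 1.5 (heavy tail);
#' and a protection field averaging 15% of the surface (the order of the
#' global terrestrial protected estate).
#'
#' @param n_species Number of species (>= 2).
#' @param seed Integer master seed (< 2^31 - 10).
#' @param birth_rate Speciation rate of the pure-birth tree model (1/Ma).
#' @param status_frequencies Named proportions over LC, NT, VU, EN, CR, DD
#'   summing to 1.
#' @param range_median_cells,range_log_sd Median (cells) and log-sd of the
#'   log-normal target range-size distribution.
#' @param protection_target_mean Target global mean coverage (percent).
#' @param protection_blob_count Number of protected blobs to scatter.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_species = 1000,
                         seed = 1,
                         birth_rate = 0.05,
                         status_frequencies = c(LC = 0.568, NT = 0.08,
                                                VU = 0.09, EN = 0.08,
                                                CR = 0.04, DD = 0.142),
                         range_median_cells = 10,
                         range_log_sd = 1.5,
                         protection_target_mean = 15,
                         protection_blob_count = 60) {
  if (n_species < 2) abort("`n_species` must be >= 2")
  if (birth_rate <= 0) abort("`birth_rate` must be positive")
  if (abs(sum(status_frequencies) - 1) > 1e-9) {
    abort("`status_frequencies` must sum to 1")
  }
  bad <- setdiff(names(status_frequencies), red_list_categories)
  if (length(bad) > 0) {
    abort(sprintf("unknown categories in `status_frequencies`: %s",
                  paste(bad, collapse = ", ")))
  }
  if (range_median_cells < 1 || range_log_sd < 0) {
    abort("range-size parameters out of range")
  }
  if (protection_target_mean < 0 || protection_target_mean > 100) {
    abort("`protection_target_mean` must lie in [0, 100]")
  }
  structure(list(
    n_species = as.integer(n_species),
    seed = as.integer(seed),
    birth_rate = birth_rate,
    status_frequencies = status_frequencies,
    range_median_cells = range_median_cells,
    range_log_sd = range_log_sd,
    protection_target_mean = protection_target_mean,
    protection_blob_count = as.integer(protection_blob_count)
  ), class = "synth_config")
}

.species_labels <- function(n) {
  sprintf("sp%0*d", nchar(as.character(n)), seq_len(n))
}

# Pure-birth (Yule) tree conditioned on n tips. Starting from the root split
# (2 lineages at time 0), each speciation waits Exp(k * lambda) while k
# lineages are extant; after the n-th tip appears a final Exp(n * lambda)
# stretch is added so pendant branches are positive. Root-to-tip depth is
# therefore sum_{k=2..n} Exp(k lambda), with expectation
# (1/lambda) * sum_{k=2..n} 1/k.
.sim_yule <- function(n, lambda, labels) {
  n_lin <- 2L * n - 2L
  parent_lin <- integer(n_lin)   # 0 = root
  t_birth <- numeric(n_lin)
  t_end <- rep(NA_real_, n_lin)
  active <- c(1L, 2L)
  n_created <- 2L
  t <- 0
  k <- 2L
  while (k < n) {
    t <- t + rexp(1, rate = k * lambda)
    pick <- active[sample.int(k, 1L)]
    t_end[pick] <- t
    ch <- c(n_created + 1L, n_created + 2L)
    parent_lin[ch] <- pick
    t_birth[ch] <- t
    n_created <- n_created + 2L
    active <- c(active[active != pick], ch)
    k <- k + 1L
  }
  t <- t + rexp(1, rate = n * lambda)
  t_end[active] <- t
  # assemble the ape edge structure: every lineage is one edge
  is_tip <- seq_len(n_lin) %in% active
  node_of <- integer(n_lin)
  node_of[active] <- seq_len(n)          # tips 1..n in creation order
  node_of[!is_tip] <- n + 1L + seq_len(n - 2L)  # internal nodes n+2..2n-1
  root <- n + 1L
  parent_node <- ifelse(parent_lin == 0L, root, node_of[pmax(parent_lin, 1L)])
  tr <- list(
    edge = cbind(parent_node, node_of),
    edge.length = t_end - t_birth,
    tip.label = labels,
    Nnode = n - 1L
  )
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate an ensemble of dated ultrametric trees
#'
#' Pure-birth (Yule) trees over a shared species label set, branch lengths
#' in Ma, emulating a posterior sample of phylogenies. Deterministic per
#' config seed.
#'
#' @param cfg A [synth_config()].
#' @param n_trees Number of trees.
#' @return A [tree_ensemble()].
#' @export
simulate_trees <- function(cfg, n_trees = 100) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(cfg$seed)
  labels <- .species_labels(cfg$n_species)
  trees <- purrr::map(seq_len(n_trees), function(i) {
    .sim_yule(cfg$n_species, cfg$birth_rate, labels)
  })
  tree_ensemble(trees)
}

#' Simulate Red List statuses
#'
#' Multinomial category assignment (including a DD fraction) under the
#' configured frequencies. Deterministic per config seed.
#'
#' @param cfg A [synth_config()].
#' @return Tibble with `species` and `category`.
#' @export
simulate_statuses <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(cfg$seed + 1L)
  freq <- cfg$status_frequencies
  tibble(
    species = .species_labels(cfg$n_species),
    category = sample(names(freq), cfg$n_species, replace = TRUE,
                      prob = as.numeric(freq))
  )
}

# spreading-dye growth of one contiguous range (4-connected, no wrap)
.spread_dye <- function(grid, size, start) {
  nr <- grid$n_rows; nc <- grid$n_cols
  occupied <- logical(grid$n_cells)
  in_frontier <- logical(grid$n_cells)
  sel <- integer(size)
  frontier <- integer(0)
  cur <- start
  for (i in seq_len(size)) {
    occupied[cur] <- TRUE
    in_frontier[cur] <- FALSE
    sel[i] <- cur
    r <- (cur - 1L) %/% nc; cc <- (cur - 1L) %% nc
    nbrs <- c(if (r > 0L) cur - nc, if (r < nr - 1L) cur + nc,
              if (cc > 0L) cur - 1L, if (cc < nc - 1L) cur + 1L)
    nbrs <- nbrs[!occupied[nbrs] & !in_frontier[nbrs]]
    if (length(nbrs) > 0) {
      in_frontier[nbrs] <- TRUE
      frontier <- c(frontier, nbrs)
    }
    frontier <- frontier[!occupied[frontier]]
    if (i == size) break
    if (length(frontier) == 0) break  # grid exhausted
    j <- sample.int(length(frontier), 1L)
    cur <- frontier[j]
    frontier <- frontier[-j]
  }
  sel[sel > 0L]
}

#' Simulate contiguous gridded species ranges
#'
#' For every species, draws a target range size from the configured
#' log-normal (clipped to at least one cell and at most the grid size) and
#' grows a 4-connected contiguous range by spreading-dye from a uniformly
#' placed seed cell. Deterministic per config seed.
#'
#' @param cfg A [synth_config()].
#' @param grid An [build_reference_grid()] grid.
#' @return A [assemble_presence()] presence matrix.
#' @export
simulate_ranges <- function(cfg, grid) {
  stopifnot(inherits(cfg, "synth_config"), inherits(grid, "equal_area_grid"))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(cfg$seed + 2L)
  n <- cfg$n_species
  sizes <- round(rlnorm(n, meanlog = log(cfg$range_median_cells),
                        sdlog = cfg$range_log_sd))
  sizes <- pmin(pmax(sizes, 1), grid$n_cells)
  starts <- sample.int(grid$n_cells, n, replace = TRUE)
  labels <- .species_labels(n)
  occ <- purrr::map2(seq_len(n), sizes, function(i, sz) {
    cells <- .spread_dye(grid, sz, starts[i])
    tibble(species = labels[i], cell = cells)
  })
  suppressMessages(
    assemble_presence(grid, bind_rows(occ), species = labels)
  )
}

#' Simulate a per-cell protection-coverage field
#'
#' Scatters rectangular and circular protected blobs over the projected
#' frame, rasterizes their union to percent coverage per cell, then
#' calibrates the field multiplicatively (with clipping at 100%) so the
#' global mean lands on the configured target. Deterministic per config
#' seed.
#'
#' @param cfg A [synth_config()].
#' @param grid An [build_reference_grid()] grid.
#' @return A `coverage_grid`.
#' @export
simulate_protection <- function(cfg, grid) {
  stopifnot(inherits(cfg, "synth_config"), inherits(grid, "equal_area_grid"))
  target <- cfg$protection_target_mean
  if (target == 0) return(coverage_grid(grid, numeric(grid$n_cells)))
  if (target == 100) return(coverage_grid(grid, rep(100, grid$n_cells)))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(cfg$seed + 3L)
  nb <- cfg$protection_blob_count
  total_area <- grid$n_cells * grid$cell_size_km^2
  mean_blob <- target / 100 * total_area / nb
  areas <- rlnorm(nb, meanlog = log(mean_blob) - 0.5, sdlog = 1)
  cx <- runif(nb, 0, grid$width_km)
  cy <- runif(nb, 0, grid$height_km)
  circle <- runif(nb) < 0.5
  rings <- purrr::map(seq_len(nb), function(i) {
    if (circle[i]) {
      buffer_point(cx[i], cy[i], areas[i])
    } else {
      aspect <- exp(runif(1, -0.7, 0.7))
      w <- sqrt(areas[i] * aspect); h <- areas[i] / w
      cbind(cx[i] + c(-w, w, w, -w) / 2, cy[i] + c(-h, -h, h, h) / 2)
    }
  })
  cov <- coverage_per_cell(rings, grid)$coverage$coverage
  # calibrate the mean to the target (multiplicative, then additive nudge)
  for (it in 1:20) {
    m <- mean(cov)
    if (m == 0 || abs(m - target) < 0.1) break
    cov <- pmin(100, cov * target / m)
  }
  for (it in 1:20) {
    m <- mean(cov)
    if (abs(m - target) < 0.1) break
    cov <- pmin(100, pmax(0, cov + (target - m)))
  }
  coverage_grid(grid, cov)
}
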