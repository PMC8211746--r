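test_that("synth_config validates the study conditions", {
  cfg <- synth_config(n_species = 10, seed = 3)
  expect_s3_class(cfg, "synth_config")
  expect_error(synth_config(n_species = 1), ">= 2")
  expect_error(synth_config(status_frequencies = c(LC = 0.5, DD = 0.4)),
               "sum to 1")
  expect_error(synth_config(protection_target_mean = 120), "\\[0, 100\\]")
  expect_error(synth_config(birth_rate = 0), "positive")
})

test_that("simulated trees are ultrametric, labelled, and seed-deterministic", {
  cfg <- synth_config(n_species = 20, seed = 5)
  e1 <- simulate_trees(cfg, 3)
  e2 <- simulate_trees(cfg, 3)
  expect_identical(vapply(unclass(e1), ape::write.tree, character(1)),
                   vapply(unclass(e2), ape::write.tree, character(1)))
  for (tr in unclass(e1)) {
    expect_true(ape::is.ultrametric(tr, tol = 1e-9))
    expect_equal(sort(tr$tip.label), sort(sprintf("sp%02d", 1:20)))
    expect_true(all(tr$edge.length >= 0))
  }
  # different seeds diverge
  e3 <- simulate_trees(synth_config(n_species = 20, seed = 6), 1)
  expect_false(identical(ape::write.tree(e1[[1]]), ape::write.tree(e3[[1]])))
})

test_that("mean Yule depth matches the closed-form expectation", {
  cfg <- synth_config(n_species = 50, seed = 8, birth_rate = 1)
  ens <- simulate_trees(cfg, 200)
  depths <- vapply(unclass(ens), function(tr)
    max(ape::node.depth.edgelength(tr)), numeric(1))
  expected <- sum(1 / (2:50))  # sum of Exp(k) waiting-time means, lambda = 1
  se <- stats::sd(depths) / sqrt(length(depths))
  expect_lt(abs(mean(depths) - expected), 4 * se + 1e-9)
})

test_that("status sampling follows the configured frequencies", {
  all_lc <- synth_config(n_species = 50, seed = 2,
                         status_frequencies = c(LC = 1))
  expect_true(all(simulate_statuses(all_lc)$category == "LC"))
  all_dd <- synth_config(n_species = 50, seed = 2,
                         status_frequencies = c(DD = 1))
  st <- simulate_statuses(all_dd)
  expect_true(all(st$category == "DD"))

  freq <- c(LC = 0.5, NT = 0.1, VU = 0.15, EN = 0.1, CR = 0.05, DD = 0.1)
  big <- synth_config(n_species = 10000, seed = 9, status_frequencies = freq)
  tab <- table(simulate_statuses(big)$category) / 10000
  for (cat in names(freq)) {
    se <- sqrt(freq[[cat]] * (1 - freq[[cat]]) / 10000)
    expect_lt(abs(tab[[cat]] - freq[[cat]]), 3 * se)
  }
  # determinism
  expect_identical(simulate_statuses(big), simulate_statuses(big))
})

test_that("simulated ranges are contiguous with the configured size profile", {
  g <- custom_grid(30, 40, 100)
  one <- synth_config(n_species = 30, seed = 4, range_median_cells = 1,
                      range_log_sd = 0)
  pm1 <- simulate_ranges(one, g)
  expect_true(all(Matrix::colSums(pm1$mat) == 1))

  cfg <- synth_config(n_species = 50, seed = 4, range_median_cells = 8,
                      range_log_sd = 1)
  pm <- simulate_ranges(cfg, g)
  expect_identical(pm$mat, simulate_ranges(cfg, g)$mat)
  # 4-connected contiguity of every range
  for (j in seq_len(10)) {
    cells <- which(as.vector(pm$mat[, j]))
    visited <- cells[1]
    frontier <- cells[1]
    while (length(frontier) > 0) {
      cur <- frontier[1]; frontier <- frontier[-1]
      r <- (cur - 1) %/% g$n_cols; cc <- (cur - 1) %% g$n_cols
      nb <- c(if (r > 0) cur - g$n_cols, if (r < g$n_rows - 1) cur + g$n_cols,
              if (cc > 0) cur - 1, if (cc < g$n_cols - 1) cur + 1)
      new <- setdiff(intersect(nb, cells), visited)
      visited <- c(visited, new)
      frontier <- c(frontier, new)
    }
    expect_setequal(visited, cells)
  }
})

test_that("range-size distribution hits the configured median", {
  g <- custom_grid(40, 60, 100)
  cfg <- synth_config(n_species = 1000, seed = 10, range_median_cells = 10,
                      range_log_sd = 1)
  pm <- simulate_ranges(cfg, g)
  med <- median(Matrix::colSums(pm$mat))
  expect_gte(med, 8)
  expect_lte(med, 12)
})

test_that("simulated protection fields are calibrated and deterministic", {
  g <- custom_grid(20, 30, 100)
  z <- simulate_protection(synth_config(n_species = 5, seed = 1,
                                        protection_target_mean = 0), g)
  expect_true(all(z$coverage$coverage == 0))
  f <- simulate_protection(synth_config(n_species = 5, seed = 1,
                                        protection_target_mean = 100), g)
  expect_true(all(f$coverage$coverage == 100))

  cfg <- synth_config(n_species = 5, seed = 11, protection_target_mean = 20,
                      protection_blob_count = 30)
  cov <- simulate_protection(cfg, g)
  expect_identical(cov$coverage, simulate_protection(cfg, g)$coverage)
  m <- mean(cov$coverage$coverage)
  expect_gte(m, 18)
  expect_lte(m, 22)
  expect_true(all(cov$coverage$coverage >= 0 & cov$coverage$coverage <= 100))
})

test_that("raising a species' threat raises HEDGE and lowers LEDGE", {
  cfg <- synth_config(n_species = 25, seed = 12)
  tr <- simulate_trees(cfg, 1)[[1]]
  model <- extinction_model()
  cats <- rep("LC", 25)
  names(cats) <- sort(tr$tip.label)
  p_lc <- stats::setNames(extinction_probability(cats, model), names(cats))
  for (sp in sample(names(cats), 5)) {
    p_cr <- p_lc
    p_cr[sp] <- extinction_probability("CR", model)
    h0 <- hedge_scores(tr, p_lc); h1 <- hedge_scores(tr, p_cr)
    l0 <- ledge_scores(tr, p_lc); l1 <- ledge_scores(tr, p_cr)
    expect_gt(h1$HEDGE[h1$species == sp], h0$HEDGE[h0$species == sp])
    expect_lt(l1$LEDGE[l1$species == sp], l0$LEDGE[l0$species == sp])
  }
})

test_that("generators leave the caller's random stream untouched", {
  cfg <- synth_config(n_species = 10, seed = 13)
  set.seed(77)
  before <- .Random.seed
  invisible(simulate_statuses(cfg))
  expect_identical(.Random.seed, before)
})
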