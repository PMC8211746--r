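test_that("expected PD, HEDGE, LEDGE, ED and EDGE reproduce the worked tree", {
  expect_equal(expected_pd(t3, p_half), 2.75, tolerance = 1e-12)
  expect_equal(expected_pd(t3, c(A = 0, B = 0, C = 0)), 5, tolerance = 1e-12)
  expect_equal(expected_pd(t3, c(A = 1, B = 1, C = 1)), 0, tolerance = 1e-12)

  h <- hedge_scores(t3, p_half)
  expect_equal(h$HEDGE[h$species == "A"], 0.75, tolerance = 1e-12)
  l <- ledge_scores(t3, p_half)
  expect_equal(l$LEDGE[l$species == "A"], 0.75, tolerance = 1e-12)

  # a secure species has zero HEDGE; a secure sister shields the stem
  h0 <- hedge_scores(t3, c(A = 0.5, B = 0, C = 0))
  expect_equal(h0$HEDGE[h0$species == "A"], 0.5, tolerance = 1e-12)
  expect_equal(h0$HEDGE[h0$species == "B"], 0, tolerance = 1e-12)
  l0 <- ledge_scores(t3, c(A = 0.5, B = 0, C = 0))
  expect_equal(l0$LEDGE[l0$species == "A"], 0.5, tolerance = 1e-12)
  l1 <- ledge_scores(t3, c(A = 1, B = 0.5, C = 0.5))
  expect_equal(l1$LEDGE[l1$species == "A"], 0, tolerance = 1e-12)

  ed <- evolutionary_distinctiveness(t3)
  expect_equal(ed$ED[match(c("A", "B", "C"), ed$species)], c(1.5, 1.5, 2),
               tolerance = 1e-12)
  expect_equal(edge_score(1.5, 2), log(2.5) + 2 * log(2), tolerance = 1e-12)
  expect_equal(edge_score(0, 0), 0)
  expect_equal(edge_score(exp(1) - 1, 1), 1 + log(2), tolerance = 1e-12)
  expect_error(edge_score(-1, 0), ">= 0")
  expect_error(edge_score(1, 5), "0..4")
})

test_that("expected_pd matches brute-force enumeration over outcomes", {
  set.seed(11)
  for (rep in 1:8) {
    tr <- random_tree(sample(3:7, 1))
    p <- random_p(tr)
    expect_equal(expected_pd(tr, p), expected_pd_enum(tr, p),
                 tolerance = 1e-10)
  }
})

test_that("per-branch HEDGE/LEDGE equal the two-evaluation definitions", {
  set.seed(12)
  for (rep in 1:40) {
    tr <- random_tree(sample(3:12, 1))
    p <- random_p(tr)
    h <- hedge_scores(tr, p)
    l <- ledge_scores(tr, p)
    base <- expected_pd(tr, p)
    for (sp in sample(tr$tip.label, min(4, length(tr$tip.label)))) {
      p0 <- p; p0[sp] <- 0
      p1 <- p; p1[sp] <- 1
      expect_equal(h$HEDGE[h$species == sp], expected_pd(tr, p0) - base,
                   tolerance = 1e-10)
      expect_equal(l$LEDGE[l$species == sp], base - expected_pd(tr, p1),
                   tolerance = 1e-10)
    }
  }
})

test_that("expected_pd is monotone non-increasing in every coordinate", {
  set.seed(13)
  for (rep in 1:10) {
    tr <- random_tree(6)
    p <- random_p(tr, pin = FALSE)
    base <- expected_pd(tr, p)
    sp <- sample(tr$tip.label, 1)
    up <- p; up[sp] <- min(1, p[sp] + 0.3)
    expect_lte(expected_pd(tr, up), base + 1e-12)
  }
})

test_that("fair-proportion ED partitions total PD", {
  set.seed(14)
  for (rep in 1:10) {
    tr <- random_tree(sample(3:20, 1))
    ed <- evolutionary_distinctiveness(tr)
    expect_equal(sum(ed$ED), sum(tr$edge.length), tolerance = 1e-10)
  }
  two <- ape::read.tree(text = "(A:1,B:1);")
  expect_equal(evolutionary_distinctiveness(two)$ED, c(1, 1))
  star <- ape::read.tree(text = "(A:3,B:3,C:3,D:3);")
  expect_equal(evolutionary_distinctiveness(star)$ED, rep(3, 4))
})

test_that("HEDGE and LEDGE are bounded by the species' root-path length", {
  set.seed(15)
  for (rep in 1:10) {
    tr <- random_tree(sample(4:10, 1))
    p <- random_p(tr)
    h <- hedge_scores(tr, p)
    l <- ledge_scores(tr, p)
    for (sp in tr$tip.label) {
      bound <- total_pd(tr, sp)
      expect_lte(h$HEDGE[h$species == sp], bound + 1e-12)
      expect_lte(l$LEDGE[l$species == sp], bound + 1e-12)
    }
  }
})

test_that("median_over_trees aggregates per species with the even-count rule", {
  ens1 <- tree_ensemble(list(t3))
  expect_equal(median_over_trees(ens1, evolutionary_distinctiveness),
               dplyr::arrange(evolutionary_distinctiveness(t3), species))

  # two trees differing in one branch length: median is the mid-point
  t3b <- ape::read.tree(text = "((A:1,B:1):1,C:4);")
  ens2 <- tree_ensemble(list(t3, t3b))
  med <- median_over_trees(ens2, evolutionary_distinctiveness)
  expect_equal(med$ED[med$species == "C"], 3)  # mean of 2 and 4

  # jittered clones stay within the jitter envelope
  set.seed(16)
  jit <- lapply(1:20, function(i) {
    tr <- t3
    tr$edge.length <- tr$edge.length * stats::runif(4, 0.95, 1.05)
    tr
  })
  med <- median_over_trees(tree_ensemble(jit), evolutionary_distinctiveness)
  base <- evolutionary_distinctiveness(t3)
  expect_true(all(abs(med$ED / base$ED[match(med$species, base$species)] - 1)
                  <= 0.05 + 1e-9))
})

test_that("top_fraction applies the floor rule with deterministic ties", {
  tb <- tibble::tibble(species = sprintf("s%04d", 1:5477),
                       score = sample(5477))
  expect_length(top_fraction(tb, 0.25), 1369)

  tb8 <- tibble::tibble(species = letters[1:8], score = 8:1)
  expect_identical(top_fraction(tb8, 0.25), c("a", "b"))
  expect_identical(sort(top_fraction(tb8, 1)), letters[1:8])

  # cut inside a tie block: exactly floor(f*n) members, label-ordered
  tbt <- tibble::tibble(species = letters[1:10],
                        score = c(9, rep(5, 8), 1))
  expect_identical(top_fraction(tbt, 0.25), c("a", "b"))
  expect_error(top_fraction(tb8, 0), "\\(0, 1\\]")
  expect_error(top_fraction(tb8, 1.2), "\\(0, 1\\]")
})

test_that("rank_correlation is mid-rank Spearman on matched species", {
  a <- tibble::tibble(species = letters[1:4], s = c(1, 2, 3, 4))
  b <- tibble::tibble(species = letters[1:4], s = c(1, 3, 2, 4))
  expect_equal(rank_correlation(a, a), 1)
  rev <- tibble::tibble(species = letters[1:4], s = c(4, 3, 2, 1))
  expect_equal(rank_correlation(a, rev), -1)
  expect_equal(rank_correlation(a, b), 0.8)
  # matching is by label, not row order
  b2 <- b[c(3, 1, 4, 2), ]
  expect_equal(rank_correlation(a, b2), 0.8)
  expect_error(rank_correlation(a, tibble::tibble(species = letters[2:5],
                                                  s = 1:4)), "same item set")
})

test_that("set_overlap counts shared members as a percentage", {
  expect_equal(set_overlap(letters[1:4], letters[1:4]), 100)
  expect_equal(set_overlap(letters[1:4], letters[5:8]), 0)
  expect_equal(set_overlap(letters[1:4], letters[3:6]), 50)
  expect_error(set_overlap(character(0), character(0)), "non-empty")
  expect_error(set_overlap(letters[1:3], letters[1:4]), "equal sizes")
})
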