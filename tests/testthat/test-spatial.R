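test_that("the reference grid construction and cell addressing behave", {
  g <- custom_grid(2, 3, 100)
  expect_equal(g$n_cells, 6)
  expect_equal(cell_id(g, 0, 0), 1L)
  expect_equal(cell_id(g, 1, 2), 6L)
  rc <- cell_rowcol(g, 1:6)
  expect_equal(cell_id(g, rc$row, rc$col), 1:6)
  expect_error(cell_id(g, 2, 0), "outside")

  r <- cell_rect(g, 1)  # north-west cell
  expect_equal(c(r$xmin, r$xmax, r$ymin, r$ymax), c(0, 100, 100, 200))
  expect_equal((r$xmax - r$xmin) * (r$ymax - r$ymin), g$cell_size_km^2)

  expect_error(build_reference_grid(cell_size_km = -1), "positive")
  expect_error(build_reference_grid(lat_max = -60, lat_min = 90), "below")
  # the whole band in one row
  g1 <- build_reference_grid(cell_size_km = 14000)
  expect_equal(g1$n_rows, 1L)
})

test_that("assemble_presence builds a deduplicated sparse matrix", {
  g <- custom_grid(1, 2, 100)
  pm <- suppressMessages(assemble_presence(
    g, tibble::tibble(species = c("A", "A", "B"), cell = c(1, 1, 2))))
  expect_equal(Matrix::nnzero(pm$mat), 2)

  # row/col dialect (0-based, row-major)
  pm2 <- assemble_presence(
    g, tibble::tibble(species = "A", row = 0, col = 1))
  expect_true(pm2$mat[2, 1])

  # zero-range species retained and reported
  expect_message(
    assemble_presence(g, tibble::tibble(species = "A", cell = 1),
                      species = c("A", "B")),
    "zero occupied cells")

  expect_error(assemble_presence(g, tibble::tibble(species = "A", cell = 3)),
               "grid")
  expect_error(assemble_presence(g, tibble::tibble(species = "A", cell = 1),
                                 species = "B"), "outside the species list")
})

test_that("range sizes are the presence-matrix column sums", {
  g <- custom_grid(1, 3, 100)
  pm <- make_pm(g, list(A = 1:2, B = 2, C = 1:3))
  rs <- range_sizes(pm)
  expect_equal(rs$range_size[match(c("A", "B", "C"), rs$species)], c(2, 1, 3))
  pm0 <- make_pm(g, list(A = 1), species = c("A", "B"))
  expect_warning(rs0 <- range_sizes(pm0), "zero cells")
  expect_equal(rs0$range_size[rs0$species == "B"], 0)
})

test_that("species-based cell scores follow their definitions", {
  g <- custom_grid(1, 2, 100)
  # A only in cell 1, B in both, C only in cell 2
  pm <- make_pm(g, list(A = 1, B = 1:2, C = 2))
  risk <- species_risk_table(c("A", "B", "C"), c("CR", "LC", "VU"), c(1, 2, 1))
  sc <- species_cell_scores(pm, risk)
  expect_equal(sc$SR, c(2, 2))
  expect_equal(sc$TSR, c(1, 1))   # CR in cell 1, VU in cell 2
  # median range size = 1, strict inequality: no species is "rare"
  expect_equal(sc$RSR, c(0, 0))
  expect_equal(sc$SWR, c(1 + 1 / 2, 1 / 2 + 1))
  expect_true(all(sc$TSR <= sc$SR) && all(sc$RSR <= sc$SR))

  # empty cell scores zero; a single 1-cell endemic has SWR 1
  g3 <- custom_grid(1, 3, 100)
  pm3 <- make_pm(g3, list(A = 1))
  r3 <- species_risk_table("A", "LC", 1)
  sc3 <- species_cell_scores(pm3, r3)
  expect_equal(sc3$SWR, c(1, 0, 0))
  expect_equal(sc3$SR[2:3], c(0, 0))

  expect_error(species_cell_scores(pm, species_risk_table("A", "LC", 1)),
               "missing from the risk table")
})

test_that("SWR summed over cells counts the occurring species", {
  set.seed(21)
  g <- custom_grid(5, 8, 100)
  occ <- lapply(1:30, function(i) sort(sample(g$n_cells, sample(1:10, 1))))
  names(occ) <- sprintf("sp%02d", 1:30)
  pm <- make_pm(g, occ)
  risk <- species_risk_table(names(occ), rep("LC", 30), lengths(occ))
  sc <- species_cell_scores(pm, risk)
  expect_equal(sum(sc$SWR), 30, tolerance = 1e-10)
})

test_that("PD cell scores use the rooted convention per subset", {
  g <- custom_grid(1, 3, 100)
  pm <- make_pm(g, list(A = c(1, 2), B = 1, C = 1))
  risk <- species_risk_table(c("A", "B", "C"), c("LC", "LC", "LC"), c(2, 1, 1))
  sc <- pd_cell_scores(pm, t3, risk)
  expect_equal(sc$PD, c(5, 2, 0))    # all species; only A; empty
  expect_equal(sc$TPD, c(0, 0, 0))   # nothing threatened
  risk2 <- species_risk_table(c("A", "B", "C"), c("EN", "LC", "LC"), c(2, 1, 1))
  sc2 <- pd_cell_scores(pm, t3, risk2)
  expect_equal(sc2$TPD, c(2, 2, 0))  # A alone, rooted path = 2
  expect_true(all(sc2$TPD <= sc2$PD + 1e-12))
})

test_that("phylogenetic endemism divides branches by their cell ranges", {
  g <- custom_grid(1, 2, 100)
  pm <- make_pm(g, list(A = 1, B = 1:2, C = 2))
  pwr <- phylogenetic_endemism(pm, t3)
  expect_equal(pwr$PWR, c(2, 3), tolerance = 1e-12)
  expect_equal(sum(pwr$PWR), total_pd(t3, c("A", "B", "C")), tolerance = 1e-12)

  # everything in one cell concentrates the whole PD there
  pm1 <- make_pm(custom_grid(1, 2, 100), list(A = 1, B = 1, C = 1))
  pwr1 <- phylogenetic_endemism(pm1, t3)
  expect_equal(pwr1$PWR, c(5, 0))
})

test_that("PWR summed over cells equals the PD of occurring branches", {
  set.seed(22)
  for (rep in 1:5) {
    tr <- random_tree(sample(5:12, 1))
    pm <- random_pm(tr, n_cells = 5)
    occurring <- pm$species[Matrix::colSums(pm$mat) > 0]
    idx <- branch_leaf_index(tr)
    expected <- sum(idx$length[vapply(idx$leaves, function(l)
      any(l %in% occurring), logical(1))])
    pwr <- suppressWarnings(phylogenetic_endemism(pm, tr))
    expect_equal(sum(pwr$PWR), expected, tolerance = 1e-9)
  }
})

test_that("top-set richness counts present members", {
  g <- custom_grid(1, 2, 100)
  pm <- make_pm(g, list(A = 1, B = 1:2, C = 2))
  expect_equal(top_set_richness(pm, c("A", "C"))[[2]], c(1, 1))
  expect_equal(top_set_richness(pm, pm$species)[[2]],
               species_cell_scores(pm, species_risk_table(
                 pm$species, rep("LC", 3), c(1, 2, 1)))$SR)
  expect_equal(top_set_richness(pm, character(0))[[2]], c(0L, 0L))
  expect_error(top_set_richness(pm, "Z"), "unknown species")
})

test_that("GexpPD and LexpPD reproduce the worked cells and reduce to HEDGE/LEDGE", {
  g <- custom_grid(1, 4, 100)
  pm <- make_pm(g, list(A = c(1, 2), B = c(2, 3), C = 3))
  gx <- gexp_pd(pm, t3, p_half)
  lx <- lexp_pd(pm, t3, p_half)
  # empty cell
  expect_equal(gx$GexpPD[4], 0)
  expect_equal(lx$LexpPD[4], 0)
  # singleton cells equal the species score
  expect_equal(gx$GexpPD[1], 0.75, tolerance = 1e-12)  # {A} -> HEDGE_A
  expect_equal(lx$LexpPD[1], 0.75, tolerance = 1e-12)  # {A} -> LEDGE_A
  # cell {A,B}
  expect_equal(gx$GexpPD[2], 1.25, tolerance = 1e-12)
  # cell {B,C}: loss of everything but A
  expect_equal(lx$LexpPD[2],
               expected_pd(t3, p_half) - expected_pd(t3, c(A = 1, B = 1, C = 0.5)),
               tolerance = 1e-12)
  pm_all <- make_pm(custom_grid(1, 1, 100), list(A = 1, B = 1, C = 1))
  expect_equal(lexp_pd(pm_all, t3, p_half)$LexpPD, 2.75, tolerance = 1e-12)
})

test_that("cell expected-PD scores equal two-evaluation oracles with bounds", {
  set.seed(23)
  for (rep in 1:15) {
    tr <- random_tree(sample(3:12, 1))
    p <- random_p(tr)
    pm <- random_pm(tr, n_cells = 4)
    gx <- gexp_pd(pm, tr, p)
    lx <- lexp_pd(pm, tr, p)
    h <- hedge_scores(tr, p); l <- ledge_scores(tr, p)
    base <- expected_pd(tr, p)
    for (cc in seq_len(pm$grid$n_cells)) {
      present <- pm$species[as.vector(pm$mat[cc, ])]
      p0 <- p; p0[present] <- 0
      p1 <- p; p1[present] <- 1
      expect_equal(gx$GexpPD[cc], expected_pd(tr, p0) - base, tolerance = 1e-10)
      expect_equal(lx$LexpPD[cc], base - expected_pd(tr, p1), tolerance = 1e-10)
      if (length(present) > 0) {
        hs <- h$HEDGE[h$species %in% present]
        ls <- l$LEDGE[l$species %in% present]
        expect_gte(gx$GexpPD[cc], max(hs) - 1e-10)
        expect_lte(gx$GexpPD[cc], sum(hs) + 1e-10)
        expect_gte(lx$LexpPD[cc], sum(ls) - 1e-10)
        expect_lte(lx$LexpPD[cc], base + 1e-10)
      }
    }
  }
})

test_that("proportion maps mask undefined cells instead of zeroing them", {
  num <- tibble::tibble(cell = 1:3, TSR = c(1, 0, 0))
  den <- tibble::tibble(cell = 1:3, SR = c(4, 2, 0))
  pr <- proportion_map(num, den)
  expect_equal(pr[[2]], c(0.25, 0, NA))
  all_thr <- proportion_map(tibble::tibble(cell = 1:2, TSR = c(3, 2)),
                            tibble::tibble(cell = 1:2, SR = c(3, 2)))
  expect_equal(all_thr[[2]], c(1, 1))
  expect_error(proportion_map(num, den[1:2, ]), "grid mismatch")
})

test_that("hotspots take the floor of the defined-cell count", {
  sc <- tibble::tibble(cell = 1:1000, v = stats::runif(1000))
  expect_length(hotspots(sc), 25)
  # undefined cells are excluded from the ranking base
  sc$v[1:200] <- NA
  expect_length(hotspots(sc), 20)
  # all equal: lowest ids win with a warning
  eq <- tibble::tibble(cell = 1:100, v = 1)
  expect_warning(hs <- hotspots(eq, fraction = 0.05), "ties")
  expect_identical(hs, 1:5)
  expect_error(hotspots(tibble::tibble(cell = 1:2, v = c(NA, NA))),
               "undefined")
  expect_error(hotspots(sc, fraction = 1), "\\(0, 1\\)")
})

test_that("cell PD agrees with the field-standard implementation", {
  skip_if_not_installed("picante")
  set.seed(24)
  tr <- random_tree(8)
  pm <- random_pm(tr, n_cells = 5)
  risk <- species_risk_table(pm$species, rep("LC", 8),
                             Matrix::colSums(pm$mat))
  got <- pd_cell_scores(pm, tr, risk)$PD
  samp <- as.matrix(pm$mat) * 1
  colnames(samp) <- pm$species
  rownames(samp) <- paste0("cell", seq_len(nrow(samp)))
  ref <- suppressWarnings(picante::pd(samp, tr, include.root = TRUE))$PD
  ref[rowSums(samp) == 0] <- 0
  expect_equal(got, ref, tolerance = 1e-9)
})
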