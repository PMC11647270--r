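## Random-walk placement, condition regions, allocation, aggregation.

test_that("a single spot lands on one valid position", {
  lay <- placeSpots(1, 10, 10, seed = 1)
  expect_equal(nOccupied(lay), 1)
  expect_true(validObject(lay))
})

test_that("placements are unique, in bounds and mostly one connected blob", {
  fracs <- vapply(1:50, function(s) {
    lay <- placeSpots(200, 30, 30, seed = s)
    expect_true(validObject(lay))  # uniqueness + bounds via class validity
    comp <- spotbench:::hexComponents(lay@row, lay@col)
    max(tabulate(comp)) / length(comp)
  }, numeric(1))
  ## tissues are contiguous with a relatively small number of holes
  expect_gte(mean(fracs), 0.9)
})

test_that("capacity and trial limits are enforced", {
  expect_error(placeSpots(101, 10, 10, seed = 1), "capacity")
})

test_that("condition regions partition the tissue, balanced and contiguous", {
  for (s in 1:50) {
    lay <- assignConditions(placeSpots(150, 25, 25, seed = s), seed = s + 500)
    cond <- lay@condition
    expect_false(anyNA(cond))
    expect_lte(abs(sum(cond == "A") - sum(cond == "B")), 1)
    ## within the tissue's main connected blob each region is contiguous
    ## (satellite islands get whatever label repair leaves them with)
    tissue_comp <- spotbench:::hexComponents(lay@row, lay@col)
    main <- which(tissue_comp == which.max(tabulate(tissue_comp)))
    for (lab in c("A", "B")) {
      idx <- main[cond[main] == lab]
      if (length(idx))
        expect_equal(max(spotbench:::hexComponents(lay@row[idx],
                                                   lay@col[idx])), 1)
    }
  }
})

test_that("all cells in a spot share the spot's condition", {
  fix <- smallTissue()
  sc_cond <- as.character(SummarizedExperiment::colData(fix$sc)$condition)
  names(sc_cond) <- colnames(fix$sc)
  df <- fix$assignment$cells
  spot_cond <- as.character(fix$layout@condition)[df$spot]
  expect_identical(unname(sc_cond[df$cell]), spot_cond)
})

test_that("uniform high-density occupancy matches the Poisson zero class", {
  prior <- makeSCPrior(30, 2, seed = 41)
  cfg <- simConfig(n_genes = 30, n_cell_types = 2, n_spots = 200,
                   array_rows = 30, array_cols = 30, n_cells_per_type = 700,
                   uniformity_prob = 1, density_high_prob = 1,
                   density_high_rate = 4)
  sim <- simulateSC(prior, cfg, seed = 42)
  lay <- assignConditions(placeSpots(200, 30, 30, seed = 43), seed = 44)
  asg <- allocateCells(sim$sc, lay, cfg, seed = 45)
  occ <- mean(asg$composition[, "ct01"] > 0)
  expect_equal(occ, 1 - exp(-4), tolerance = 3 * sqrt(0.02 * 0.98 / 200) / (1 - exp(-4)))
})

test_that("sparse types occupy at most the configured subset of spots", {
  prior <- makeSCPrior(30, 2, seed = 51)
  cfg <- simConfig(n_genes = 30, n_cell_types = 2, n_spots = 150,
                   array_rows = 25, array_cols = 25, n_cells_per_type = 400,
                   uniformity_prob = 0, sparse_subset_frac = 0.02)
  sim <- simulateSC(prior, cfg, seed = 52)
  lay <- assignConditions(placeSpots(150, 25, 25, seed = 53), seed = 54)
  asg <- allocateCells(sim$sc, lay, cfg, seed = 55)
  for (t in colnames(asg$composition)) {
    for (cc in c("A", "B")) {
      region <- which(lay@condition == cc)
      cap <- max(3, ceiling(0.02 * length(region)))
      expect_lte(sum(asg$composition[region, t] > 0), cap)
    }
  }
})

test_that("an exhausted cell pool reports the shortfall", {
  prior <- makeSCPrior(30, 2, seed = 61)
  cfg <- simConfig(n_genes = 30, n_cell_types = 2, n_spots = 150,
                   array_rows = 25, array_cols = 25, n_cells_per_type = 10,
                   uniformity_prob = 1, density_high_prob = 1)
  sim <- simulateSC(prior, cfg, seed = 62)
  lay <- assignConditions(placeSpots(150, 25, 25, seed = 63), seed = 64)
  expect_error(allocateCells(sim$sc, lay, cfg, seed = 65),
               "pool exhausted.*shortfall")
})

test_that("spot counts are the sums of their cells' counts", {
  fix <- smallTissue()
  counts <- SummarizedExperiment::assay(fix$sc)
  df <- fix$assignment$cells
  ## conservation over the whole tissue
  expect_equal(sum(spotCounts(fix$spot)),
               sum(counts[, df$cell]))
  ## additivity for one multi-cell spot
  tab <- table(df$spot)
  s <- as.integer(names(tab)[tab > 1][1])
  bc <- spotBarcode(fix$layout@row[s], fix$layout@col[s])
  expect_equal(as.numeric(spotCounts(fix$spot)[, bc]),
               as.numeric(Matrix::rowSums(counts[, df$cell[df$spot == s],
                                                 drop = FALSE])))
  ## background spots are all-zero with zero composition at ST-M
  bg <- !inTissue(fix$spot)
  expect_true(all(Matrix::colSums(spotCounts(fix$spot))[bg] == 0))
  expect_true(all(rowSums(spotComposition(fix$spot))[bg] == 0))
})
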