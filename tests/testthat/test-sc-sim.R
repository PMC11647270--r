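## Prior estimation from labelled counts, the NB simulator and its QC.

makeToyCounts <- function(n_genes, cells_per_group, mean = 6, seed = 1) {
  ## deterministic-ish Poisson counts; totals ~ n_genes * mean >> 500
  withr::with_seed(seed,
    matrix(rpois(n_genes * cells_per_group, mean), nrow = n_genes,
           dimnames = list(sprintf("g%03d", 1:n_genes), NULL)))
}

test_that("cell types below 50 cells in any donor are dropped", {
  G <- 100
  counts <- cbind(makeToyCounts(G, 60, seed = 1), makeToyCounts(G, 60, seed = 2),
                  makeToyCounts(G, 49, seed = 3))
  labels <- rep(c("common", "common", "rare"), times = c(60, 60, 49))
  donors <- rep(c("d1", "d2", "d1"), times = c(60, 60, 49))
  ## 'common' spans two donors with 60 cells each; 'rare' has 49 in d1 only
  expect_error(estimatePrior(counts, labels, donors), "fewer than 2")
  ## with no donor structure, both types pass except 'rare' (49 < 50)
  prior <- estimatePrior(cbind(counts, makeToyCounts(G, 55, seed = 4)),
                         c(labels, rep("other", 55)))
  expect_false("rare" %in% cellTypes(prior))
  expect_setequal(cellTypes(prior), c("common", "other"))
})

test_that("cells under 500 counts are excluded from the estimate", {
  G <- 100
  counts <- cbind(makeToyCounts(G, 60, seed = 5), makeToyCounts(G, 60, seed = 6))
  labels <- rep(c("t1", "t2"), each = 60)
  ## shrink one t1 cell to 499 counts but give it a huge signature count
  bad <- integer(G); bad[1] <- 499
  counts[, 1] <- bad
  prior <- estimatePrior(counts, labels)
  ## had the 499-count cell been kept, gene g001's t1 mean would be ~8
  expect_lt(priorMeans(prior)["g001", "t1"], 8)
})

test_that("Poisson data yields large method-of-moments dispersions", {
  G <- 100
  counts <- cbind(makeToyCounts(G, 2500, mean = 6, seed = 7),
                  makeToyCounts(G, 2500, mean = 6, seed = 8))
  labels <- rep(c("t1", "t2"), each = 2500)
  prior <- estimatePrior(counts, labels)
  ## Poisson limit: size -> infinity; moment estimate should be very large
  expect_gt(median(priorDispersions(prior)), 20)
})

test_that("p_de = 0 gives an all-null ground truth", {
  prior <- makeSCPrior(50, 2, seed = 1)
  sim <- simulateSC(prior, simConfig(n_genes = 50, n_cell_types = 2,
                                     p_de = 0, n_cells_per_type = 30),
                    seed = 2)
  expect_false(any(isDE(sim$gt)))
  expect_true(all(trueLogFC(sim$gt) == 0))
  expect_equal(sim$gt@meanB, sim$gt@meanA)
})

test_that("simulated counts realize the parameterized fold changes and moments", {
  prior <- makeSCPrior(80, 2, seed = 11, marker_fraction = 0,
                       baseline_meanlog = log(2), baseline_sdlog = 0.5)
  cfg <- simConfig(n_genes = 80, n_cell_types = 2, p_de = 0.25,
                   logfc_magnitude = 1, n_cells_per_type = 2000)
  sim <- simulateSC(prior, cfg, seed = 12)
  counts <- SummarizedExperiment::assay(sim$sc)
  cd <- SummarizedExperiment::colData(sim$sc)

  ## a DE gene with logFC 1: empirical B/A mean ratio -> 2 within 3 SE
  de <- which(trueLogFC(sim$gt)[, "ct01"] == 1)
  g <- de[which.max(sim$gt@meanA[de, "ct01"])]
  selA <- cd$cell_type == "ct01" & cd$condition == "A"
  selB <- cd$cell_type == "ct01" & cd$condition == "B"
  mA <- mean(counts[g, selA]); mB <- mean(counts[g, selB])
  muA <- sim$gt@meanA[g, "ct01"]; phi <- priorDispersions(prior)[g]
  se_ratio <- 2 * sqrt((muA + muA^2 / phi) / (muA^2 * 2000) +
                       (2 * muA + 4 * muA^2 / phi) / (4 * muA^2 * 2000))
  expect_lt(abs(mB / mA - 2), 3 * se_ratio)

  ## per-gene sample variance tracks the NB moment mu + mu^2/size
  nonde <- which(!isDE(sim$gt)[, "ct01"] & prior@mean[, "ct01"] > 1)[1:10]
  v_emp <- apply(as.matrix(counts[nonde, selA]), 1, var)
  mu <- prior@mean[nonde, "ct01"]
  v_theory <- mu + mu^2 / priorDispersions(prior)[nonde]
  expect_lt(median(abs(v_emp - v_theory) / v_theory), 0.25)
})

test_that("re-estimating a prior from simulated data recovers the type means", {
  prior <- makeSCPrior(300, 2, seed = 21, baseline_meanlog = log(2),
                       baseline_sdlog = 0.8)
  cfg <- simConfig(n_genes = 300, n_cell_types = 2, p_de = 0,
                   n_cells_per_type = 4000)
  sim <- simulateSC(prior, cfg, seed = 22)
  est <- estimatePrior(as.matrix(SummarizedExperiment::assay(sim$sc)),
                       SummarizedExperiment::colData(sim$sc)$cell_type)
  shared <- intersect(rownames(priorMeans(est)), rownames(priorMeans(prior)))
  for (t in c("ct01", "ct02")) {
    truth <- priorMeans(prior)[shared, t]
    hit <- truth > 0.5
    rel <- abs(priorMeans(est)[shared, t][hit] - truth[hit]) / truth[hit]
    expect_lt(max(rel), 0.10)
  }
})

test_that("the QC report flags a constructed top-100 violation", {
  ## 100 genes with strong empirical fold change, only 55 of them true DEGs
  G <- 200
  meanA <- rep(5, G)
  lfc <- numeric(G); lfc[1:55] <- 2
  gt <- new("GroundTruth",
            isDE = matrix(lfc != 0, G, 1, dimnames = list(sprintf("g%03d", 1:G), "ct01")),
            logFC = matrix(lfc, G, 1, dimnames = list(sprintf("g%03d", 1:G), "ct01")),
            meanA = matrix(meanA, G, 1, dimnames = list(sprintf("g%03d", 1:G), "ct01")),
            meanB = matrix(meanA * 2^lfc, G, 1,
                           dimnames = list(sprintf("g%03d", 1:G), "ct01")))
  ## counts give ALL first 100 genes an empirical ratio of 4
  empB <- meanA; empB[1:100] <- meanA[1:100] * 4
  nc <- 40
  counts <- cbind(matrix(rep(meanA, nc), G), matrix(rep(empB, nc), G))
  dimnames(counts) <- list(rownames(isDE(gt)), sprintf("c%03d", 1:(2 * nc)))
  sc <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE)),
    colData = S4Vectors::DataFrame(
      cell_type = rep("ct01", 2 * nc),
      condition = factor(rep(c("A", "B"), each = nc)),
      row.names = colnames(counts)))
  rep_ <- qcGroundTruth(sc, gt)
  expect_lt(rep_@top100Congruence, 0.6)
  expect_false(rep_@criteria[["top100"]])
  expect_false(qcPassed(rep_))
})

test_that("the SC baseline subsample is a permutation at full pool size", {
  prior <- makeSCPrior(30, 2, seed = 31)
  sim <- simulateSC(prior, simConfig(n_genes = 30, n_cell_types = 2,
                                     n_cells_per_type = 25), seed = 32)
  pool <- ncol(sim$sc)
  sub <- inflateSCBaseline(sim$sc, pool, seed = 33)
  expect_setequal(colnames(sub), colnames(sim$sc))
  expect_error(inflateSCBaseline(sim$sc, pool + 1, seed = 1), "pool")
  expect_error(inflateSCBaseline(sim$sc, 0, seed = 1), "positive")
  expect_identical(colnames(inflateSCBaseline(sim$sc, 10, seed = 34)),
                   colnames(inflateSCBaseline(sim$sc, 10, seed = 34)))
})
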