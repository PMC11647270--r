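## Leakage and downsampling artifact models.

test_that("leakage kernels are row-normalized with no self-weight", {
  xy <- spotbench:::hexXY(c(0, 1, 2), c(0, 1, 2))
  W <- leakageKernel(xy, xy, kernel_sd = 2, self = 1:3)
  expect_equal(rowSums(W), rep(1, 3))
  expect_true(all(diag(W) == 0))
})

test_that("zero bleed is the identity and any bleed conserves transcripts", {
  fix <- smallTissue()
  no <- applyLeakage(fix$spot, bleed_rate = 0, seed = 1)
  expect_equal(as.matrix(spotCounts(no)), as.matrix(spotCounts(fix$spot)))
  expect_identical(stageTag(no), "ST-L")
  leaked <- applyLeakage(fix$spot, bleed_rate = 0.4, kernel_sd = 2, seed = 2)
  expect_identical(sum(spotCounts(leaked)), sum(spotCounts(fix$spot)))
  expect_true(min(spotCounts(leaked)) >= 0)
})

test_that("background spots near tissue receive the kernel-expected leakage", {
  ## two tissue spots with large counts so the Poisson cap never triggers
  counts <- rbind(g1 = c(200, 200), g2 = c(100, 300))
  ds <- toySpotDataset(counts, rows = c(3, 4), cols = c(3, 4),
                       array_rows = 8, array_cols = 8,
                       condition = c("A", "B"))
  bleed <- 0.1; ksd <- 1.5
  cd <- SummarizedExperiment::colData(ds)
  xy <- spotbench:::hexXY(cd$array_row, cd$array_col)
  src <- which(cd$in_tissue)
  W <- leakageKernel(xy[src, , drop = FALSE], xy, ksd, self = src)
  expected <- bleed * (as.matrix(spotCounts(ds)[, src]) %*% W)  # genes x dest

  nrep <- 200
  acc <- matrix(0, nrow(ds), ncol(ds))
  for (r in seq_len(nrep))
    acc <- acc + as.matrix(spotCounts(applyLeakage(ds, bleed, ksd, seed = r)))
  got <- acc / nrep
  ## compare received counts at the 12 highest-expectation background spots
  bg <- which(!cd$in_tissue)
  exp_bg <- colSums(expected)[bg]
  top <- bg[order(exp_bg, decreasing = TRUE)[1:12]]
  for (s in top) {
    e <- sum(expected[, s])
    se <- sqrt(e / nrep)  # Poisson-scale Monte-Carlo error
    expect_lt(abs(sum(got[, s]) - e), 4 * se + 0.05)
  }
})

test_that("downsampled gene draws follow the original proportions", {
  counts <- matrix(c(100, 300, 600), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), NULL))
  ds <- toySpotDataset(counts, rows = 0, cols = 0, condition = "A")
  nrep <- 2000
  draws <- vapply(seq_len(nrep), function(r) {
    as.numeric(spotCounts(downsampleSpots(ds, 0.1, seed = r))[, 1])
  }, numeric(3))
  m <- rowMeans(draws)
  expected <- c(10, 30, 60)
  se <- apply(draws, 1, sd) / sqrt(nrep)
  expect_true(all(abs(m - expected) < 3 * se))
})

test_that("accurate downsampling never exceeds the original counts", {
  fix <- smallTissue()
  d <- downsampleSpots(fix$spot, 0.3, accurate = TRUE, seed = 3)
  expect_true(all(spotCounts(d) <= spotCounts(fix$spot)))
  ## all-zero positions stay all-zero
  zero <- Matrix::colSums(spotCounts(fix$spot)) == 0
  expect_true(all(Matrix::colSums(spotCounts(d))[zero] == 0))
})

test_that("the aggregate retained fraction matches the requested depth", {
  fix <- smallTissue()
  for (pct in c(0.5, 0.05)) {
    d <- downsampleSpots(fix$spot, pct, seed = 4)
    expect_equal(sum(spotCounts(d)) / sum(spotCounts(fix$spot)), pct,
                 tolerance = 0.05)
  }
})

test_that("a single candidate depth is returned as-is", {
  fix <- smallTissue()
  ref <- spotSummary(downsampleSpots(fix$spot, 0.05, seed = 5))
  expect_equal(as.numeric(selectDownsamplePct(fix$spot, 0.07, ref, seed = 6)),
               0.07)
  ks <- attr(selectDownsamplePct(fix$spot, c(0.10, 0.05, 0.01), ref, seed = 7),
             "ks")
  expect_length(ks, 3)
})

test_that("leak and downsample stages compose into ST-LD", {
  fix <- smallTissue()
  stl <- applyLeakage(fix$spot, 0.2, 2, seed = 8)
  expect_identical(stageTag(downsampleSpots(stl, 0.1, seed = 9)), "ST-LD")
  std <- downsampleSpots(fix$spot, 0.1, seed = 10)
  expect_identical(stageTag(std), "ST-D")
})
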