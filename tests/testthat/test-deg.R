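## Filtering, loglib, spot-group selection, native tests, voting, BH.

test_that("filtering drops sparse genes and cell-less spots, then refilters", {
  counts <- rbind(g1 = c(5, 4, 3), g2 = c(1, 1, 0), g3 = c(0, 0, 4))
  ds <- toySpotDataset(counts, rows = 0:2, cols = 0:2,
                       condition = c("A", "A", "B"),
                       composition = cbind(ct01 = c(2L, 1L, 0L)))
  ## spot 3 holds no cells (leak-only); g2 totals 2 (< 3); g3 then has 0 counts
  f <- filterDataset(ds)
  expect_identical(rownames(f), "g1")
  expect_equal(ncol(f), 2)
  ## idempotence on an already-clean dataset
  f2 <- filterDataset(f)
  expect_identical(dim(f2), dim(f))
})

test_that("loglib normalization is depth-invariant with log(pseudocount) zeros", {
  counts <- Matrix::Matrix(rbind(g1 = c(0, 100), g2 = c(50, 9900)),
                           sparse = TRUE)
  v <- normalizeLoglib(counts, scale = 1e4, pseudocount = 1)
  expect_equal(unname(v[1, 1]), 0)
  expect_equal(unname(v[1, 2]), log(101))  # 100 of 10^4 at scale 10^4
  doubled <- normalizeLoglib(2 * counts)
  expect_equal(as.matrix(doubled), as.matrix(v))
  expect_error(normalizeLoglib(cbind(c(0, 0))), "zero total")
})

test_that("spot groups follow the containing/single/regional contracts", {
  comp <- cbind(ct01 = c(1L, 3L, 0L, 2L), ct02 = c(0L, 2L, 4L, 2L))
  ds <- toySpotDataset(matrix(1, 2, 4), rows = c(0, 1, 2, 3),
                       cols = c(0, 1, 2, 3),
                       condition = c("A", "A", "B", "B"), composition = comp)
  occ <- which(inTissue(ds))
  u <- selectTestUnits(ds, "ct01", "containing")
  expect_equal(unname(u$A), occ[1:2]); expect_equal(unname(u$B), occ[4])
  ## single: strict majority only (spots 1 and 2 favour ct01; spot 4 ties 2-2)
  s <- selectTestUnits(ds, "ct01", "single")
  expect_equal(unname(s$A), occ[1:2]); expect_length(s$B, 0)
  expect_true(s$flagged)
  ## regional: identical groups for every cell type
  r1 <- selectTestUnits(ds, "ct01", "regional")
  r2 <- selectTestUnits(ds, "ct02", "regional")
  expect_identical(r1[c("A", "B")], r2[c("A", "B")])
  expect_equal(unname(r1$A), occ[1:2]); expect_equal(unname(r1$B), occ[3:4])
})

test_that("the Welch t-test matches the closed-form oracle and the NA rule", {
  ## oracle: direct t CDF evaluation via stats::t.test
  a <- c(1, 2, 3, 4); b <- c(5, 6, 7, 8)
  expect_equal(degTtest(a, b), t.test(a, b)$p.value)
  ## frozen from the oracle: t = 4.382, Welch df = 6
  expect_equal(degTtest(a, b), 0.004659, tolerance = 1e-4)
  ## identical constant groups: untestable, p = 1
  expect_equal(degTtest(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_equal(degTtest(1, c(1, 2, 3)), 1)  # n too small
  ## matrix input, order invariance
  m <- matrix(rnorm(40), 4)
  expect_equal(degTtest(m[, 1:5], m[, 6:10]),
               degTtest(m[, 5:1], m[, c(8, 10, 9, 6, 7)]))
})

test_that("Wilcoxon p-values match the exhaustive rank-permutation oracle", {
  a <- c(1, 2, 3, 4); b <- c(10, 11, 12, 13)
  ## oracle: enumerate all C(8,4) group assignments of the pooled ranks
  pooled <- c(a, b)
  W_obs <- sum(rank(pooled)[1:4]) - 4 * 5 / 2
  combos <- combn(8, 4)
  W_all <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]) - 10)
  p_exact <- mean(abs(W_all - 8) >= abs(W_obs - 8))  # center = n1*n2/2
  expect_equal(p_exact, 2 / 70)
  expect_equal(degWilcoxon(a, b), 2 / 70)
  ## tie-heavy data falls back to the corrected normal approximation
  expect_true(is.finite(degWilcoxon(c(0, 0, 1, 1), c(1, 1, 2, 2))))
  expect_equal(degWilcoxon(c(2, 2, 2), c(2, 2, 2)), 1)
})

test_that("the interaction model detects ratio-dependent DE and stays calibrated", {
  set.seed(77)
  n <- 400
  cond <- rep(c("A", "B"), each = n / 2)
  ratio <- runif(n)
  ## expression responds to condition only through the focal type's ratio
  expr <- 5 + 2 * (cond == "B") * ratio + rnorm(n)
  expect_lt(degLmCovariate(expr, cond, ratio), 0.01)
  ## constant ratio: rank-deficient design is flagged with p = 1
  flat <- degLmCovariate(expr, cond, rep(0.5, n))
  expect_equal(as.numeric(flat), 1)
  expect_true(attr(flat, "flagged"))
  ## null calibration: interaction p uniform under no DE
  null_expr <- matrix(rnorm(500 * n, 5), nrow = 500)
  p <- degLmCovariate(null_expr, cond, ratio)
  expect_gt(ks.test(p, punif)$p.value, 0.01)
})

test_that("majority voting requires half plus one of the methods", {
  calls6 <- matrix(FALSE, 2, 6)
  calls6[1, 1:4] <- TRUE  # 4 of 6 call gene 1
  calls6[2, 1:3] <- TRUE  # 3 of 6 call gene 2
  expect_equal(majorityVote(calls6), c(TRUE, FALSE))
  expect_equal(majorityVote(cbind(c(TRUE, TRUE), c(TRUE, FALSE))),
               c(TRUE, FALSE))  # 2 methods: both required
  expect_error(majorityVote(cbind(TRUE)), ">= 2")
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bhAdjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.42), 0.42)
  p <- runif(50)
  expect_true(all(bhAdjust(p) >= p))
})

test_that("runDEG returns a tidy table with consistent calls", {
  fix <- smallTissue()
  f <- filterDataset(fix$spot)
  res <- runDEG(f, methods = c("ttest", "wilcoxon", "majority"),
                input_mode = "containing", alpha = 0.01)
  expect_setequal(unique(res$method), c("ttest", "wilcoxon", "majority"))
  expect_equal(nrow(res), 3 * 3 * nrow(f))  # methods x types x genes
  tt <- res[res$method == "ttest", ]
  expect_true(all(tt$call == (tt$p_adj <= 0.01)))
  expect_true(all(tt$p_adj >= tt$p))
  ## lm route runs on all spots with ground-truth ratios
  lm_res <- runDEG(f, methods = "lm", input_mode = "containing")
  expect_true(all(lm_res$p >= 0 & lm_res$p <= 1))
})
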