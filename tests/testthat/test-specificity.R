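## Gene-cell specificity scores, selection, subset BH, matched baselines.

test_that("mean specificity follows the scaled-mean formula", {
  s <- meanSpecificity(rbind(g1 = c(A = 3, B = 1), g2 = c(A = 0, B = 2),
                             g3 = c(A = 0, B = 0)))
  expect_equal(specScores(s)["g1", ], c(A = 0.75, B = 0.25))
  expect_equal(specScores(s)["g2", "B"], 1)  # single-type gene
  expect_false(s@scored[3])                  # all-zero gene unscored
  expect_identical(argmaxType(s), c("A", "B", NA))
})

test_that("frequency specificity normalizes detection rates", {
  counts <- rbind(g1 = c(1, 0, 1, 0, 2, 0, 0, 0),
                  g2 = c(0, 0, 0, 0, 0, 0, 0, 0),
                  g3 = c(1, 2, 3, 4, 5, 6, 7, 8))
  labels <- rep(c("A", "B"), each = 4)
  s <- frequencySpecificity(counts, labels)
  ## detection 0.5 in A, 0.25 in B -> 2/3, 1/3
  expect_equal(specScores(s)["g1", ], c(A = 2 / 3, B = 1 / 3))
  expect_false(s@scored[2])
  expect_equal(specScores(s)["g3", ], c(A = 0.5, B = 0.5))
  three <- frequencySpecificity(rbind(g = rep(1, 9)), rep(c("a", "b", "c"), 3))
  expect_equal(as.numeric(specScores(three)), rep(1 / 3, 3))
})

test_that("scored rows sum to one and permuting types permutes scores", {
  set.seed(9)
  m <- matrix(rexp(60), 20, 3, dimnames = list(sprintf("g%02d", 1:20),
                                               c("x", "y", "z")))
  s <- meanSpecificity(m)
  expect_equal(rowSums(specScores(s)), setNames(rep(1, 20), rownames(m)))
  perm <- meanSpecificity(m[, c(3, 1, 2)])
  expect_equal(specScores(perm), specScores(s)[, c(3, 1, 2)])
})

test_that("threshold selection keeps scored genes and attributes the argmax", {
  s <- meanSpecificity(rbind(g1 = c(a = 8, b = 2), g2 = c(a = 5, b = 5),
                             g3 = c(a = 0, b = 0), g4 = c(a = 0, b = 3)))
  all_sel <- selectGenes(s, 0)
  expect_setequal(all_sel$gene, c("g1", "g2", "g4"))  # unscored g3 never kept
  strict <- selectGenes(s, 1)
  expect_identical(strict$gene, "g4")  # only the single-type-exclusive gene
  ## tie at the argmax goes to the lexicographically smallest type id
  expect_identical(all_sel$cell_type[all_sel$gene == "g2"], "a")
  expect_identical(selectGenes(s, 0.8)$gene, c("g1", "g4"))
})

test_that("subset-restricted BH reduces to plain BH on the full set", {
  set.seed(11)
  p <- setNames(runif(40), sprintf("g%02d", 1:40))
  s <- meanSpecificity(matrix(rexp(80), 40, 2,
                              dimnames = list(names(p), c("a", "b"))))
  full <- selectGenes(s, 0)
  res <- priorSelectedDEG(p, full, alpha = 0.05)
  expect_equal(res$p_adj, unname(bhAdjust(p[res$gene])))
  ## dropping the genes with the largest raw p never increases a
  ## surviving gene's adjusted p (the subset-BH benefit of selection)
  keep <- full[full$gene %in% names(sort(p)[1:20]), ]
  res_sub <- priorSelectedDEG(p, keep, alpha = 0.05)
  shared <- intersect(res_sub$gene, res$gene)
  expect_true(all(res_sub$p_adj[match(shared, res_sub$gene)] <=
                  res$p_adj[match(shared, res$gene)] + 1e-12))
  expect_warning(out <- priorSelectedDEG(p, full[0, ]), "empty selection")
  expect_equal(nrow(out), 0)
})

test_that("matched baselines honour size, reproducibility and list reuse", {
  s <- meanSpecificity(matrix(rexp(60), 30, 2,
                              dimnames = list(sprintf("g%02d", 1:30),
                                              c("a", "b"))))
  all_genes <- matchedBaselines(s, 30, "random", seed = 3)
  expect_setequal(all_genes$gene, sprintf("g%02d", 1:30))
  expect_identical(matchedBaselines(s, 10, "random", seed = 4)$gene,
                   matchedBaselines(s, 10, "random", seed = 4)$gene)
  ext <- c("g01", "g02", "g03")
  grown <- matchedBaselines(s, 7, "external_list", external_list = ext,
                            seed = 5)
  expect_equal(nrow(grown), 7)
  expect_true(all(grown$gene %in% ext))    # list reused with repeats
  expect_true(any(duplicated(grown$gene)))
  shrunk <- matchedBaselines(s, 2, "external_list", external_list = ext,
                             seed = 6)
  expect_false(any(duplicated(shrunk$gene)))
})
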