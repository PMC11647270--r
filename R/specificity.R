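## Gene-cell specificity scores, threshold selection with argmax attribution,
## subset-restricted FDR, and matched baseline selections.

## Shared constructor: row-normalize a genes x types non-negative matrix.
makeSpecificity <- function(raw, metric) {
  stopifnot(all(raw >= 0))
  den <- rowSums(raw)
  scored <- den > 0
  score <- raw
  score[scored, ] <- raw[scored, , drop = FALSE] / den[scored]
  score[!scored, ] <- NA_real_
  ## argmax with ties broken toward the lexicographically smallest type id
  ord <- order(colnames(raw))
  amax <- rep(NA_character_, nrow(raw))
  if (any(scored)) {
    sorted <- score[scored, ord, drop = FALSE]
    amax[scored] <- colnames(sorted)[max.col(sorted, ties.method = "first")]
  }
  score[!scored, ] <- 0
  new("SpecificityScores", score = score, metric = metric,
      argmaxType = amax, scored = scored)
}

#' Mean specificity: type means scaled by their sum
#'
#' For gene g and cell type c, the score is the average expression of g in c
#' divided by the sum of g's average expression over all cell types, so each
#' scored gene's row sums to one and a gene expressed in a single type
#' scores 1 there. Genes with zero expression in every type have no defined
#' score and are flagged unscored.
#'
#' @param type_means Genes x cell types matrix of average expression per
#'   cell (e.g. `priorMeans()` of an [SCReference-class], or empirical type
#'   means of a single-cell dataset).
#' @return A [SpecificityScores-class] with metric `"mean"`.
#' @examples
#' meanSpecificity(rbind(g1 = c(A = 3, B = 1)))
#' @export
meanSpecificity <- function(type_means) {
  makeSpecificity(as.matrix(type_means), "mean")
}

#' Frequency specificity: detection rates scaled by their sum
#'
#' The per-type detection rate of a gene (fraction of cells of that type
#' with a nonzero count) normalized across cell types. A gene never detected
#' anywhere is unscored; a gene detected in every cell of every one of n
#' types scores 1/n everywhere.
#'
#' @param counts Genes x cells count matrix.
#' @param labels Cell-type label per cell (every type needs >= 1 cell).
#' @return A [SpecificityScores-class] with metric `"frequency"`.
#' @export
frequencySpecificity <- function(counts, labels) {
  labels <- as.character(labels)
  types <- sort(unique(labels))
  det <- vapply(types, function(t)
    as.numeric(Matrix::rowMeans(counts[, labels == t, drop = FALSE] > 0)),
    numeric(nrow(counts)))
  if (is.null(dim(det))) det <- matrix(det, nrow = 1)
  dimnames(det) <- list(rownames(counts), types)
  makeSpecificity(det, "frequency")
}

#' Select genes by specificity threshold with argmax attribution
#'
#' A gene is kept when its maximum specificity score reaches `threshold`
#' (inclusive) and is attributed to exactly one cell type — its argmax (ties
#' toward the lexicographically smallest type id) — so that downstream each
#' gene is evaluated for only one cell type, if at all. Unscored genes can
#' never be selected.
#'
#' @param scores A [SpecificityScores-class].
#' @param threshold Cutoff in `[0, 1]`; 0 keeps every scored gene.
#' @return `data.frame` with columns `gene`, `cell_type` (the attribution)
#'   and `score` (the argmax score).
#' @export
selectGenes <- function(scores, threshold) {
  stopifnot(is(scores, "SpecificityScores"),
            threshold >= 0, threshold <= 1)
  mx <- apply(scores@score, 1, max)
  keep <- scores@scored & mx >= threshold
  data.frame(gene = rownames(scores@score)[keep],
             cell_type = scores@argmaxType[keep],
             score = mx[keep], row.names = NULL, stringsAsFactors = FALSE)
}

#' Prior-selected DEG calls with subset-restricted FDR
#'
#' The headline selection scheme: DEG p-values are computed once in regional
#' mode over all genes; selection is applied afterwards and affects the FDR
#' correction only. The BH adjustment runs with `m` equal to the number of
#' selected genes, and each selected gene is called for its argmax cell type
#' alone. Selecting all genes reduces to plain BH; shrinking the selection
#' never increases a surviving gene's adjusted p-value.
#'
#' @param p Named numeric vector of raw regional p-values (names = genes).
#' @param selection `data.frame` from [selectGenes()] or
#'   [matchedBaselines()].
#' @param alpha Significance level on adjusted p-values (default .01).
#' @return Tidy `data.frame` with `method`, `cell_type`, `gene`, `p`,
#'   `p_adj`, `call`; empty selection yields an empty result with a warning.
#' @export
priorSelectedDEG <- function(p, selection, alpha = 0.01) {
  stopifnot(!is.null(names(p)))
  selection <- selection[selection$gene %in% names(p), , drop = FALSE]
  if (nrow(selection) == 0) {
    warning("empty selection; no genes to test")
    return(data.frame(method = character(0), cell_type = character(0),
                      gene = character(0), p = numeric(0),
                      p_adj = numeric(0), call = logical(0)))
  }
  praw <- p[selection$gene]
  padj <- bhAdjust(praw)
  data.frame(method = "prior_selected", cell_type = selection$cell_type,
             gene = selection$gene, p = unname(praw), p_adj = unname(padj),
             call = unname(padj <= alpha), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Baseline gene selections matched in size
#'
#' Builds comparison selections of exactly `k` genes: `random` draws `k`
#' scored genes uniformly without replacement; `external_list` draws from a
#' supplied gene list without repetition, or — when `k` exceeds the list —
#' uses the entire list and lets genes repeat to reach `k`. Genes are
#' attributed to their argmax cell type from `scores` so the evaluation is
#' comparable with the prior-based selection.
#'
#' @param scores A [SpecificityScores-class] (attribution source).
#' @param k Number of genes to select (>= 1).
#' @param mode `"random"` or `"external_list"`.
#' @param external_list Character vector of genes for `external_list` mode.
#' @param seed Integer seed.
#' @return `data.frame` with columns `gene`, `cell_type`, `score`.
#' @export
matchedBaselines <- function(scores, k, mode = c("random", "external_list"),
                             external_list = NULL, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(k >= 1)
  withSeed(seed, {
    genes <- if (mode == "random") {
      pool <- rownames(scores@score)[scores@scored]
      stopifnot(k <= length(pool))
      pool[sample.int(length(pool), k)]
    } else {
      stopifnot(!is.null(external_list), length(external_list) > 0)
      if (k <= length(external_list))
        external_list[sample.int(length(external_list), k)]
      else
        c(external_list,
          external_list[sample.int(length(external_list), k - length(external_list),
                                   replace = TRUE) ])
    }
    idx <- match(genes, rownames(scores@score))
    data.frame(gene = genes, cell_type = scores@argmaxType[idx],
               score = apply(scores@score[idx, , drop = FALSE], 1, max),
               row.names = NULL, stringsAsFactors = FALSE)
  })
}
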