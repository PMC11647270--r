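## Filtering, loglib normalization, native DEG tests (Welch t, Wilcoxon,
## condition x cell-ratio interaction model), majority voting, BH adjustment.

#' Filter a spot dataset before DEG analysis
#'
#' Drops genes with fewer than three total counts, spots with no allocated
#' cells (background spots keep leaked transcripts but hold no cells and are
#' removed) and spots with zero counts, then re-drops genes left with zero
#' counts — the re-filter matters mostly for leak-plus-downsample data.
#' Already-clean matrices pass through unchanged.
#'
#' @param ds A [SpotDataset-class].
#' @return The filtered [SpotDataset-class].
#' @export
filterDataset <- function(ds) {
  stopifnot(is(ds, "SpotDataset"))
  keep_gene <- Matrix::rowSums(spotCounts(ds)) >= 3
  ds <- ds[keep_gene, ]
  keep_spot <- rowSums(spotComposition(ds)) > 0 &
    Matrix::colSums(spotCounts(ds)) > 0
  ds <- ds[, keep_spot]
  ds <- ds[Matrix::rowSums(spotCounts(ds)) > 0, ]
  if (nrow(ds) == 0 || ncol(ds) == 0)
    stop("filtering removed all genes or spots", call. = FALSE)
  ds
}

#' Library-size log normalization (loglib)
#'
#' `log(count / spot_total * scale + pseudocount)`: counts are scaled to a
#' common library size and log-transformed with a pseudocount, so a zero
#' count maps to `log(pseudocount)` (0 at the default pseudocount of 1) and
#' doubling every count in a spot leaves its values unchanged.
#'
#' @param counts Genes x spots count matrix.
#' @param scale Library scale factor (default 1e4).
#' @param pseudocount Added inside the log (default 1).
#' @return Matrix of normalized values (sparse when `pseudocount == 1`).
#' @export
normalizeLoglib <- function(counts, scale = 1e4, pseudocount = 1) {
  stopifnot(scale > 0)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("spot with zero total counts; run filterDataset() first",
         call. = FALSE)
  if (pseudocount == 1 && methods::is(counts, "sparseMatrix")) {
    m <- methods::as(counts, "CsparseMatrix")
    reps <- rep.int(totals, diff(m@p))
    m@x <- log1p(m@x / reps * scale)
    m
  } else {
    m <- as.matrix(counts)
    log(sweep(m, 2, totals, "/") * scale + pseudocount)
  }
}

#' Select the spot groups a DEG test compares
#'
#' `containing`: spots with at least one cell of the focal type, split by
#' condition (the mode used for per-cell-type testing). `single`: only spots
#' predominantly composed of the focal type (strict majority), emulating
#' annotation tools that treat spots as single cells. `regional`: every
#' tissue spot of each condition regardless of composition — the same groups
#' for every cell type, and the input the specificity selection scheme is
#' built for. An empty group is flagged; the caller assigns p = 1 to all
#' genes.
#'
#' @param ds A [SpotDataset-class].
#' @param cell_type Focal cell type (ignored for `regional`).
#' @param input_mode `"containing"`, `"single"` or `"regional"`.
#' @return List with integer spot indices `A`, `B` and `flagged`.
#' @export
selectTestUnits <- function(ds, cell_type,
                            input_mode = c("containing", "single", "regional")) {
  input_mode <- match.arg(input_mode)
  comp <- spotComposition(ds)
  cond <- spotCondition(ds)
  tissue <- inTissue(ds)
  sel <- switch(input_mode,
    containing = comp[, cell_type] >= 1,
    single = {
      focal <- comp[, cell_type]
      others <- comp[, setdiff(colnames(comp), cell_type), drop = FALSE]
      focal > 0 & focal > apply(others, 1, max)
    },
    regional = tissue & rowSums(comp) > 0)
  A <- which(sel & !is.na(cond) & cond == "A")
  B <- which(sel & !is.na(cond) & cond == "B")
  list(A = A, B = B, flagged = length(A) == 0 || length(B) == 0)
}

## Row-wise Welch t-test p-values for genes x samples matrices.
## Failure modes follow the NA rule: too few samples or zero variance in
## both groups yields p = 1.
rowWelchP <- function(x, y) {
  nx <- ncol(x); ny <- ncol(y)
  G <- nrow(x)
  if (nx < 2 || ny < 2) return(rep(1, G))
  mx <- Matrix::rowMeans(x); my <- Matrix::rowMeans(y)
  vx <- (Matrix::rowMeans(x^2) - mx^2) * nx / (nx - 1)
  vy <- (Matrix::rowMeans(y^2) - my^2) * ny / (ny - 1)
  vx <- pmax(vx, 0); vy <- pmax(vy, 0)
  se2 <- vx / nx + vy / ny
  p <- rep(1, G)
  ok <- se2 > 0
  tt <- (mx[ok] - my[ok]) / sqrt(se2[ok])
  df <- se2[ok]^2 / ((vx[ok] / nx)^2 / (nx - 1) + (vy[ok] / ny)^2 / (ny - 1))
  p[ok] <- 2 * stats::pt(-abs(tt), df)
  p
}

#' Per-gene two-sided Welch t-test
#'
#' Vectorized over genes. Failures (fewer than two samples in a group, zero
#' variance in both groups) are treated as a p-value of 1, following the
#' rule that untestable genes count as non-significant.
#'
#' @param values_A,values_B Genes x spots matrices of the two groups (or
#'   numeric vectors for a single gene).
#' @return Numeric vector of two-sided p-values.
#' @examples
#' degTtest(rbind(g = c(1, 2, 3, 4)), rbind(g = c(5, 6, 7, 8)))
#' @export
degTtest <- function(values_A, values_B) {
  if (is.null(dim(values_A))) values_A <- matrix(values_A, nrow = 1)
  if (is.null(dim(values_B))) values_B <- matrix(values_B, nrow = 1)
  rowWelchP(values_A, values_B)
}

#' Per-gene two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution when both groups have at most `exact_max` samples
#' and no ties are present; otherwise the normal approximation with tie
#' correction. Failures (empty groups, all values tied across both groups)
#' are treated as a p-value of 1.
#'
#' @param values_A,values_B Genes x spots matrices (or vectors).
#' @param exact_max Largest group size for the exact distribution.
#' @return Numeric vector of two-sided p-values.
#' @export
degWilcoxon <- function(values_A, values_B, exact_max = 25) {
  if (is.null(dim(values_A))) values_A <- matrix(values_A, nrow = 1)
  if (is.null(dim(values_B))) values_B <- matrix(values_B, nrow = 1)
  nx <- ncol(values_A); ny <- ncol(values_B)
  G <- nrow(values_A)
  if (nx < 1 || ny < 1) return(rep(1, G))
  values_A <- as.matrix(values_A); values_B <- as.matrix(values_B)
  vapply(seq_len(G), function(g) {
    a <- values_A[g, ]; b <- values_B[g, ]
    p <- tryCatch(
      suppressWarnings(stats::wilcox.test(
        a, b, exact = nx <= exact_max && ny <= exact_max &&
          !anyDuplicated(c(a, b)))$p.value),
      error = function(e) NA_real_)
    if (!is.finite(p)) 1 else p
  }, numeric(1))
}

#' Per-gene condition-by-cell-ratio interaction test
#'
#' Fits `expr ~ condition + ratio + condition:ratio` per gene over all spots
#' and returns the two-sided p-value of the interaction coefficient — the
#' design used to fold (ground-truth) deconvolution cell ratios into a
#' classic DEG test. A rank-deficient design (e.g. a constant ratio) drops
#' the term: all p-values are 1 and the result is flagged via the
#' `"flagged"` attribute.
#'
#' @param expr Genes x spots matrix of expression values.
#' @param condition Factor/character of spot conditions (two levels).
#' @param cell_ratio Numeric per-spot fraction of the focal cell type.
#' @return Numeric vector of interaction p-values.
#' @export
degLmCovariate <- function(expr, condition, cell_ratio) {
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = 1)
  n <- ncol(expr)
  stopifnot(length(condition) == n, length(cell_ratio) == n)
  X <- stats::model.matrix(~ factor(condition) * cell_ratio)
  G <- nrow(expr)
  if (qr(X)$rank < ncol(X) || n <= ncol(X))
    return(structure(rep(1, G), flagged = TRUE))
  qx <- qr(X)
  Y <- t(as.matrix(expr))
  B <- qr.coef(qx, Y)
  res <- Y - X %*% B
  df <- n - ncol(X)
  s2 <- colSums(res^2) / df
  xtxi <- chol2inv(qr.R(qx))[ncol(X), ncol(X)]
  se <- sqrt(xtxi * s2)
  p <- rep(1, G)
  ok <- se > 0
  p[ok] <- 2 * stats::pt(-abs(B[ncol(X), ok] / se[ok]), df)
  structure(p, flagged = FALSE)
}

#' Majority vote across DEG methods
#'
#' A gene is a consensus DEG when at least `floor(n_methods / 2) + 1` of the
#' individual methods call it.
#'
#' @param calls Logical genes x methods matrix of per-method calls.
#' @return Logical vector of consensus calls.
#' @examples
#' majorityVote(cbind(m1 = c(TRUE, TRUE), m2 = c(TRUE, FALSE)))
#' @export
majorityVote <- function(calls) {
  calls <- as.matrix(calls)
  if (ncol(calls) < 2) stop("majority vote needs >= 2 methods", call. = FALSE)
  rowSums(calls, na.rm = TRUE) >= floor(ncol(calls) / 2) + 1
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH with monotonicity enforcement; the number of
#' hypotheses is the number of p-values passed in, which makes the
#' adjustment subset-aware: restricting to a pre-selected gene subset before
#' calling this function applies the correction with `m` equal to the subset
#' size only.
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

## Extract the per-spot (or per-cell) expression groups for one cell type.
degGroups <- function(ds, cell_type, input_mode, values) {
  if (is(ds, "SpotDataset")) {
    u <- selectTestUnits(ds, cell_type, input_mode)
    list(A = values[, u$A, drop = FALSE], B = values[, u$B, drop = FALSE],
         flagged = u$flagged)
  } else {
    ct <- colData(ds)$cell_type
    cond <- colData(ds)$condition
    A <- which(ct == cell_type & cond == "A")
    B <- which(ct == cell_type & cond == "B")
    list(A = values[, A, drop = FALSE], B = values[, B, drop = FALSE],
         flagged = length(A) == 0 || length(B) == 0)
  }
}

#' Run DEG tests per cell type
#'
#' Applies the selected native tests per cell type on a (filtered) spot
#' dataset or on a simulated single-cell dataset (where each cell acts as
#' its own `containing` unit). Raw counts are tested by default; set
#' `use_loglib = TRUE` to test loglib-normalized values instead — in
#' practice the normalization has little effect on the outcome. The `lm`
#' method uses all tissue spots with the ground-truth composition fraction
#' of the focal type as covariate; `majority` combines the other requested
#' methods. P-values are BH-adjusted per (method, cell type) and calls made
#' at `alpha`.
#'
#' @param ds A [SpotDataset-class] (after [filterDataset()]) or a
#'   SingleCellExperiment from [simulateSC()].
#' @param methods Subset of `c("ttest", "wilcoxon", "lm", "majority")`.
#' @param input_mode Spot-group selection mode (see [selectTestUnits()]).
#' @param alpha Significance level on BH-adjusted p-values (default .01).
#' @param use_loglib Test loglib-normalized values instead of raw counts.
#' @param cell_types Cell types to test (default: all in the dataset).
#' @return A tidy `data.frame` with columns `method`, `cell_type`, `gene`,
#'   `p`, `p_adj`, `call`, `flagged`.
#' @export
runDEG <- function(ds, methods = c("ttest", "wilcoxon"),
                   input_mode = "containing", alpha = 0.01,
                   use_loglib = FALSE, cell_types = NULL) {
  stopifnot(all(methods %in% c("ttest", "wilcoxon", "lm", "majority")))
  is_spot <- is(ds, "SpotDataset")
  counts <- assay(ds, "counts")
  values <- if (use_loglib) normalizeLoglib(counts) else counts
  genes <- rownames(ds)
  if (is.null(cell_types))
    cell_types <- if (is_spot) colnames(spotComposition(ds)) else
      sort(unique(colData(ds)$cell_type))
  base_methods <- setdiff(methods, "majority")

  out <- list()
  for (ct in cell_types) {
    grp <- degGroups(ds, ct, input_mode, values)
    pmat <- matrix(NA_real_, length(genes), 0)
    for (m in base_methods) {
      p <- if (grp$flagged && m != "lm") {
        rep(1, length(genes))
      } else if (m == "ttest") {
        rowWelchP(grp$A, grp$B)
      } else if (m == "wilcoxon") {
        degWilcoxon(grp$A, grp$B)
      } else {
        if (!is_spot) stop("lm method requires a SpotDataset", call. = FALSE)
        tissue <- which(inTissue(ds) & !is.na(spotCondition(ds)))
        ratio <- spotComposition(ds)[tissue, ct] /
          pmax(rowSums(spotComposition(ds)[tissue, , drop = FALSE]), 1)
        degLmCovariate(values[, tissue, drop = FALSE],
                       spotCondition(ds)[tissue], ratio)
      }
      pmat <- cbind(pmat, p)
      colnames(pmat)[ncol(pmat)] <- m
    }
    calls <- apply(pmat, 2, function(p) bhAdjust(p) <= alpha)
    if ("majority" %in% methods && ncol(pmat) >= 2)
      calls <- cbind(calls, majority = majorityVote(calls))
    for (m in colnames(pmat)) {
      out[[paste(ct, m)]] <- data.frame(
        method = m, cell_type = ct, gene = genes, p = pmat[, m],
        p_adj = bhAdjust(pmat[, m]), call = calls[, m],
        flagged = grp$flagged, stringsAsFactors = FALSE)
    }
    if ("majority" %in% colnames(calls))
      out[[paste(ct, "majority")]] <- data.frame(
        method = "majority", cell_type = ct, gene = genes, p = NA_real_,
        p_adj = NA_real_, call = calls[, "majority"], flagged = grp$flagged,
        stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
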