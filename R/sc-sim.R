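## Two-condition single-cell NB simulator, prior estimation from annotated
## counts, ground-truth QC, and the inflated SC baseline.

#' Estimate a simulation prior from annotated single-cell counts
#'
#' Applies the reference filters and returns per-(gene, cell type) means and
#' per-gene method-of-moments negative binomial dispersions. Filters, in
#' order: cell types with fewer than `min_cells_per_type` cells in any donor
#' are dropped; cells with fewer than `min_counts` total counts or at least
#' `max_mito_frac` mitochondrial counts are dropped; genes are kept only when
#' they show more than one count in at least `min_cells_detect` cells; genes
#' with mean expression below `low_mean_cutoff` are removed (the simulator
#' cannot reproduce such means faithfully and their empirical fold changes
#' would drift from the parameterized ones).
#'
#' @param counts Genes x cells count matrix (dense or sparse), with rownames.
#' @param cell_labels Cell-type label per cell.
#' @param donor_labels Optional donor label per cell; `NULL` treats the data
#'   as one donor.
#' @param mito_gene_mask Optional logical per gene marking mitochondrial
#'   genes; `NULL` skips the mitochondrial filter.
#' @param min_cells_per_type,min_counts,max_mito_frac,min_cells_detect
#'   Filter thresholds (defaults 50 cells/type/donor, 500 counts/cell, 12%
#'   mitochondrial, detection in 10 cells).
#' @param low_mean_cutoff Minimum retained mean expression (counts/cell).
#' @return An [SCReference-class].
#' @export
estimatePrior <- function(counts, cell_labels, donor_labels = NULL,
                          mito_gene_mask = NULL, min_cells_per_type = 50,
                          min_counts = 500, max_mito_frac = 0.12,
                          min_cells_detect = 10, low_mean_cutoff = 0.005) {
  stopifnot(ncol(counts) == length(cell_labels))
  if (is.null(donor_labels)) donor_labels <- rep("donor1", ncol(counts))
  stopifnot(ncol(counts) == length(donor_labels))
  cell_labels <- as.character(cell_labels)

  ## cell types present with enough cells in every donor
  tab <- table(cell_labels, donor_labels)
  keep_types <- rownames(tab)[apply(tab, 1, min) >= min_cells_per_type]
  keep_cell <- cell_labels %in% keep_types

  ## per-cell depth and mitochondrial content
  totals <- Matrix::colSums(counts)
  keep_cell <- keep_cell & totals >= min_counts
  if (!is.null(mito_gene_mask)) {
    stopifnot(length(mito_gene_mask) == nrow(counts))
    mito <- Matrix::colSums(counts[mito_gene_mask, , drop = FALSE]) /
      pmax(totals, 1)
    keep_cell <- keep_cell & mito < max_mito_frac
  }
  counts <- counts[, keep_cell, drop = FALSE]
  cell_labels <- cell_labels[keep_cell]
  surviving <- unique(cell_labels)
  if (length(surviving) < 2)
    stop("fewer than 2 cell types survive the filters", call. = FALSE)

  ## gene detection and low-mean filters
  keep_gene <- Matrix::rowSums(counts > 1) >= min_cells_detect
  keep_gene <- keep_gene & Matrix::rowMeans(counts) >= low_mean_cutoff
  counts <- counts[keep_gene, , drop = FALSE]
  if (nrow(counts) == 0) stop("no genes survive the filters", call. = FALSE)

  types <- sort(surviving)
  mu <- matrix(0, nrow(counts), length(types),
               dimnames = list(rownames(counts), types))
  num <- den <- numeric(nrow(counts))
  for (t in types) {
    sel <- cell_labels == t
    n <- sum(sel)
    m <- Matrix::rowMeans(counts[, sel, drop = FALSE])
    m2 <- Matrix::rowMeans(counts[, sel, drop = FALSE]^2)
    v <- (m2 - m^2) * n / (n - 1)
    mu[, t] <- m
    ## method of moments: var = mu + mu^2 / size  =>  size = mu^2/(var - mu)
    num <- num + n * m^2
    den <- den + n * (v - m)
  }
  size <- ifelse(den > 0, num / den, 1e8)
  size <- pmin(pmax(size, 1e-3), 1e8)
  new("SCReference", mean = mu, dispersion = size)
}

#' Simulate two-condition single cells with known DEGs
#'
#' For each cell type, a fraction `p_de` of genes is flagged differentially
#' expressed with log2 fold change `+-logfc_magnitude` (sign random, balanced
#' in expectation). Condition A cells draw counts from the prior means,
#' condition B cells from `mean * 2^logFC`; counts are negative binomial with
#' the prior's per-gene dispersion. `config$n_cells_per_type` cells are
#' simulated per cell type and condition.
#'
#' @param prior An [SCReference-class].
#' @param config A [SimConfig-class] (uses `p_de`, `logfc_magnitude`,
#'   `n_cells_per_type`).
#' @param seed Integer seed.
#' @param n_cells_per_type Optional override of the per-(type, condition)
#'   cell count.
#' @return A list with `sc` (a
#'   [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment-class]
#'   with `cell_type` and `condition` in `colData`) and `gt`
#'   (a [GroundTruth-class]).
#' @examples
#' prior <- makeSCPrior(50, 2, seed = 1)
#' sim <- simulateSC(prior, simConfig(p_de = 0.2, n_cells_per_type = 40), seed = 1)
#' @export
simulateSC <- function(prior, config, seed, n_cells_per_type = NULL) {
  stopifnot(is(prior, "SCReference"), is(config, "SimConfig"))
  p_de <- config$p_de
  stopifnot(p_de >= 0, p_de <= 1)
  mag <- config$logfc_magnitude
  n_cells <- as.integer(n_cells_per_type %||% config$n_cells_per_type)
  G <- nrow(prior@mean)
  types <- colnames(prior@mean)
  k <- length(types)

  withSeed(seed, {
    lfc <- matrix(0, G, k, dimnames = dimnames(prior@mean))
    n_de <- round(p_de * G)
    for (t in seq_len(k)) {
      de <- sample.int(G, n_de)
      lfc[de, t] <- mag * sample(c(-1, 1), n_de, replace = TRUE)
    }
    meanA <- prior@mean
    meanB <- meanA * 2^lfc
    gt <- new("GroundTruth", isDE = lfc != 0, logFC = lfc,
              meanA = meanA, meanB = meanB)

    blocks <- vector("list", 2L * k)
    cell_type <- condition <- character(0)
    b <- 0L
    for (t in seq_len(k)) {
      for (cond in c("A", "B")) {
        mu <- if (cond == "A") meanA[, t] else meanB[, t]
        m <- matrix(stats::rnbinom(G * n_cells, size = prior@dispersion,
                                   mu = mu), nrow = G)
        b <- b + 1L
        blocks[[b]] <- m
        cell_type <- c(cell_type, rep(types[t], n_cells))
        condition <- c(condition, rep(cond, n_cells))
      }
    }
    m <- do.call(cbind, blocks)
    dimnames(m) <- list(rownames(prior@mean),
                        sprintf("cell%06d", seq_len(ncol(m))))
    sc <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = Matrix::Matrix(m, sparse = TRUE)),
      colData = DataFrame(cell_type = cell_type,
                          condition = factor(condition, levels = c("A", "B")),
                          row.names = colnames(m)))
    list(sc = sc, gt = gt)
  })
}

## Per-(gene, type, condition) empirical means of an SC dataset.
scGroupMeans <- function(sc) {
  counts <- assay(sc, "counts")
  ct <- colData(sc)$cell_type
  cond <- colData(sc)$condition
  types <- sort(unique(ct))
  out <- list(A = matrix(0, nrow(counts), length(types),
                         dimnames = list(rownames(counts), types)),
              B = matrix(0, nrow(counts), length(types),
                         dimnames = list(rownames(counts), types)))
  for (t in types) for (cc in c("A", "B")) {
    sel <- ct == t & cond == cc
    out[[cc]][, t] <- Matrix::rowMeans(counts[, sel, drop = FALSE])
  }
  out
}

#' Quality-control a simulated dataset against its ground truth
#'
#' Verifies that the simulated counts are a faithful realization of the
#' parameterized ground truth via four criteria (see [QCReport-class]):
#' unanalyzable fraction, log-fold-change fidelity (0.1 log2 tolerance on
#' the mean empirical log2FC of the parameterized DEGs per cell type and
#' direction, with the per-gene violation count reported for diagnosis),
#' empirical DEG fraction (Welch t-test at p < .01; the detected fraction
#' must lie within 2 percentage points of the parameterized one) and top-100
#' congruence. Criteria 2-4 are applied only to (gene, cell type) pairs with
#' positive empirical means in both conditions. A report is always returned;
#' callers halt the pipeline when `qcPassed(report)` is `FALSE`.
#'
#' @param ds The `sc` SingleCellExperiment from [simulateSC()].
#' @param gt The matching [GroundTruth-class].
#' @param config A [SimConfig-class]; thresholds are read from `config$qc`.
#' @return A [QCReport-class].
#' @export
qcGroundTruth <- function(ds, gt, config = simConfig()) {
  qc <- config$qc
  counts <- assay(ds, "counts")
  ct <- colData(ds)$cell_type
  cond <- colData(ds)$condition
  types <- colnames(gt@isDE)
  G <- nrow(gt@isDE)
  em <- scGroupMeans(ds)
  emA <- em$A[, types, drop = FALSE]
  emB <- em$B[, types, drop = FALSE]

  ## criterion 1: unanalyzable pairs (zero empirical mean in both conditions)
  unanalyzable <- emA == 0 & emB == 0
  frac_un <- mean(unanalyzable)

  pos <- emA > 0 & emB > 0
  emp_lfc <- matrix(NA_real_, G, length(types), dimnames = dimnames(emA))
  emp_lfc[pos] <- log2(emB[pos] / emA[pos])

  ## criterion 2: mean empirical log2FC of parameterized DEGs per
  ## (type, direction) within tolerance; per-gene violations counted
  max_dev <- 0
  violations <- 0L
  for (t in seq_along(types)) {
    for (s in c(1, -1)) {
      sel <- gt@isDE[, t] & sign(gt@logFC[, t]) == s & pos[, t]
      if (!any(sel)) next
      dev <- abs(mean(emp_lfc[sel, t]) - mean(gt@logFC[sel, t]))
      max_dev <- max(max_dev, dev)
      violations <- violations +
        sum(abs(emp_lfc[sel, t] - gt@logFC[sel, t]) > qc$logfc_tol)
    }
  }

  ## criterion 3: empirical DE fraction (Welch t, p < de_alpha) vs p_de
  detected <- 0L
  for (t in seq_along(types)) {
    selA <- ct == types[t] & cond == "A"
    selB <- ct == types[t] & cond == "B"
    p <- rowWelchP(counts[, selA, drop = FALSE], counts[, selB, drop = FALSE])
    detected <- detected + sum(p < qc$de_alpha & pos[, t])
  }
  param <- sum(gt@isDE)
  de_frac_err <- abs(detected - param) / (G * length(types))
  de_rel_err <- if (param > 0) abs(detected - param) / param else 0

  ## criterion 4: congruence of the top-100 empirical |log2FC| pairs
  cand <- which(pos & !is.na(emp_lfc))
  top <- cand[order(abs(emp_lfc[cand]), decreasing = TRUE)]
  top <- top[seq_len(min(100L, length(top)))]
  congruence <- if (length(top)) mean(gt@isDE[top]) else 0

  criteria <- c(unanalyzable = frac_un <= qc$max_unanalyzable,
                logfc = max_dev <= qc$logfc_tol,
                de_count = de_frac_err < qc$de_frac_tol,
                top100 = congruence >= qc$top100_min)
  new("QCReport", fracUnanalyzable = frac_un, logfcMaxMeanDev = max_dev,
      logfcViolations = as.integer(violations), deFracError = de_frac_err,
      deCountRelError = de_rel_err, top100Congruence = congruence,
      criteria = criteria, passed = all(criteria))
}

#' Subsample single cells for the SC baseline
#'
#' Randomly selects `n_cells` cells (without replacement) from the available
#' pool so that the single-cell baseline analysed alongside the spatial
#' stages has a cell count comparable to the cells contained in a tissue;
#' the default matches the 5000-cell configuration.
#'
#' @param ds A SingleCellExperiment of simulated cells.
#' @param n_cells Number of cells to retain (default 5000).
#' @param seed Integer seed.
#' @return A SingleCellExperiment with `n_cells` columns.
#' @export
inflateSCBaseline <- function(ds, n_cells = 5000, seed) {
  if (n_cells <= 0) stop("n_cells must be positive", call. = FALSE)
  if (n_cells > ncol(ds))
    stop("n_cells (", n_cells, ") exceeds the available pool (", ncol(ds),
         "); simulate more cells", call. = FALSE)
  withSeed(seed, ds[, sample.int(ncol(ds), n_cells)])
}
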