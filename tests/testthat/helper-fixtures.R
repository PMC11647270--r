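## Shared fixtures, built once per test run.

.fixtures <- new.env()

## A small but complete tissue (ST-M) reused across test files.
smallTissue <- function() {
  if (is.null(.fixtures$small)) {
    prior <- makeSCPrior(200, 3, seed = 101)
    cfg <- simConfig(n_genes = 200, n_cell_types = 3, n_spots = 80,
                     array_rows = 20, array_cols = 20,
                     n_cells_per_type = 300)
    .fixtures$small <- c(buildTissue(prior, cfg, seed = 102, qc = FALSE),
                         list(prior = prior, cfg = cfg))
  }
  .fixtures$small
}

## Hand-built SpotDataset on a small array: a few tissue spots with given
## counts, everything else background. Used where exact counts matter.
toySpotDataset <- function(counts, rows, cols, array_rows = 8,
                           array_cols = 8, condition = NULL,
                           composition = NULL, stage = "ST-M") {
  counts <- as.matrix(counts)
  n_occ <- length(rows)
  stopifnot(ncol(counts) == n_occ, length(cols) == n_occ)
  grid_row <- rep(0:(array_rows - 1L), each = array_cols)
  grid_col <- as.integer(2L * rep(0:(array_cols - 1L), array_rows) +
                           grid_row %% 2L)
  npos <- length(grid_row)
  occ_at <- match(paste(rows, cols), paste(grid_row, grid_col))
  stopifnot(!anyNA(occ_at))
  m <- Matrix::Matrix(0, nrow(counts), npos, sparse = TRUE)
  m[, occ_at] <- counts
  barcodes <- sprintf("spot_r%03d_c%03d", grid_row, grid_col)
  genes <- rownames(counts) %||% sprintf("g%03d", seq_len(nrow(counts)))
  dimnames(m) <- list(genes, barcodes)
  if (is.null(composition))
    composition <- matrix(1L, n_occ, 1, dimnames = list(NULL, "ct01"))
  comp <- matrix(0L, npos, ncol(composition),
                 dimnames = list(barcodes, colnames(composition)))
  comp[occ_at, ] <- composition
  cond <- factor(rep(NA_character_, npos), levels = c("A", "B"))
  if (!is.null(condition)) cond[occ_at] <- condition
  in_tissue <- logical(npos)
  in_tissue[occ_at] <- TRUE
  cd <- S4Vectors::DataFrame(array_row = grid_row, array_col = grid_col,
                             in_tissue = in_tissue, condition = cond,
                             row.names = barcodes)
  cd$composition <- comp
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), colData = cd)
  out <- new("SpotDataset", sce)
  S4Vectors::metadata(out)$stage <- stage
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Mean of an evaluation metric over cell types for one method's rows.
meanMetricByType <- function(res, method, gt, evaluated, metric = "F1") {
  sub <- res[res$method == method, , drop = FALSE]
  types <- sort(unique(sub$cell_type))
  vals <- vapply(types, function(ct) {
    s <- sub[sub$cell_type == ct, ]
    truth <- stats::setNames(isDE(gt)[, ct], rownames(isDE(gt)))
    scoreCalls(stats::setNames(s$call, s$gene), truth,
               intersect(evaluated, names(truth)))[[metric]]
  }, numeric(1))
  mean(vals)
}
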