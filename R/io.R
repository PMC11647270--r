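## Plain-text readers and writers: MatrixMarket + TSV/CSV sidecars, following
## 10x Visium file conventions (matrix.mtx, genes/barcodes TSV, tissue
## positions CSV), plus TSV forms of the prior, ground truth and QC report.

#' Write a spot dataset to a directory
#'
#' Emits `matrix.mtx` (genes x positions), `genes.tsv`, `barcodes.tsv`,
#' `tissue_positions.csv` (`barcode,in_tissue,array_row,array_col`), a
#' long-form `composition.tsv` sidecar (`spot_barcode, cell_type, n_cells,
#' condition`; one row per tissue spot and cell type, zeros included) and
#' `metadata.json` (stage, file digests). The round trip through
#' [readSpotDataset()] is lossless for counts, coordinates, composition and
#' condition labels; empty spots are preserved, never dropped.
#'
#' @param ds A [SpotDataset-class].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeSpotDataset <- function(ds, dir) {
  stopifnot(is(ds, "SpotDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(methods::as(spotCounts(ds), "CsparseMatrix"), mtx)
  writeLines(rownames(ds), file.path(dir, "genes.tsv"))
  writeLines(colnames(ds), file.path(dir, "barcodes.tsv"))
  cd <- colData(ds)
  utils::write.csv(
    data.frame(barcode = colnames(ds), in_tissue = as.integer(cd$in_tissue),
               array_row = cd$array_row, array_col = cd$array_col),
    file.path(dir, "tissue_positions.csv"), row.names = FALSE, quote = FALSE)
  comp <- cd$composition
  tissue <- which(cd$in_tissue)
  long <- data.frame(
    spot_barcode = rep(colnames(ds)[tissue], each = ncol(comp)),
    cell_type = rep(colnames(comp), length(tissue)),
    n_cells = as.integer(t(comp[tissue, , drop = FALSE])),
    condition = rep(as.character(cd$condition[tissue]), each = ncol(comp)))
  utils::write.table(long, file.path(dir, "composition.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  files <- c("matrix.mtx", "genes.tsv", "barcodes.tsv",
             "tissue_positions.csv", "composition.tsv")
  jsonlite::write_json(
    list(stage = stageTag(ds) %||% "unknown",
         digests = as.list(tools::md5sum(file.path(dir, files)))),
    file.path(dir, "metadata.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a spot dataset written by [writeSpotDataset()]
#'
#' @param dir Directory containing the files, or `NULL` when giving paths.
#' @param matrix_path,positions_path Optional explicit paths overriding the
#'   standard names in `dir`.
#' @return A [SpotDataset-class].
#' @export
readSpotDataset <- function(dir = NULL, matrix_path = NULL,
                            positions_path = NULL) {
  matrix_path <- matrix_path %||% file.path(dir, "matrix.mtx")
  positions_path <- positions_path %||% file.path(dir, "tissue_positions.csv")
  base <- dirname(matrix_path)
  counts <- methods::as(Matrix::readMM(matrix_path), "CsparseMatrix")
  genes <- readLines(file.path(base, "genes.tsv"))
  barcodes <- readLines(file.path(base, "barcodes.tsv"))
  dimnames(counts) <- list(genes, barcodes)
  pos <- utils::read.csv(positions_path, stringsAsFactors = FALSE)
  if (!setequal(pos$barcode, barcodes) || nrow(pos) != length(barcodes))
    stop("barcode mismatch between matrix and positions", call. = FALSE)
  pos <- pos[match(barcodes, pos$barcode), ]

  long <- utils::read.table(file.path(base, "composition.tsv"), sep = "\t",
                            header = TRUE, stringsAsFactors = FALSE)
  types <- sort(unique(long$cell_type))
  comp <- matrix(0L, length(barcodes), length(types),
                 dimnames = list(barcodes, types))
  comp[cbind(match(long$spot_barcode, barcodes),
             match(long$cell_type, types))] <- long$n_cells
  condition <- factor(rep(NA_character_, length(barcodes)),
                      levels = c("A", "B"))
  first <- long[!duplicated(long$spot_barcode), ]
  condition[match(first$spot_barcode, barcodes)] <- first$condition

  cd <- DataFrame(array_row = pos$array_row, array_col = pos$array_col,
                  in_tissue = pos$in_tissue == 1, condition = condition,
                  row.names = barcodes)
  cd$composition <- comp
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
  out <- new("SpotDataset", sce)
  meta_path <- file.path(base, "metadata.json")
  metadata(out)$stage <- if (file.exists(meta_path))
    jsonlite::fromJSON(meta_path)$stage else "unknown"
  out
}

#' Write / read a single-cell dataset (MTX + cells TSV)
#'
#' `cells.tsv` holds `barcode, cell_type, condition`.
#'
#' @param sc SingleCellExperiment with `cell_type` and `condition` colData.
#' @param dir Directory.
#' @return `dir` (write) or a SingleCellExperiment (read).
#' @export
writeSCDataset <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(assay(sc, "counts"), "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(sc), file.path(dir, "genes.tsv"))
  utils::write.table(
    data.frame(barcode = colnames(sc),
               cell_type = colData(sc)$cell_type,
               condition = as.character(colData(sc)$condition)),
    file.path(dir, "cells.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname writeSCDataset
#' @export
readSCDataset <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                        "CsparseMatrix")
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes, cells$barcode)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = DataFrame(cell_type = cells$cell_type,
                        condition = factor(cells$condition,
                                           levels = c("A", "B")),
                        row.names = cells$barcode))
}

#' Write / read a simulation prior as TSV
#'
#' Long form: `gene, cell_type, mean, dispersion`.
#'
#' @param prior An [SCReference-class].
#' @param path TSV path.
#' @return `path` (write) or an [SCReference-class] (read).
#' @export
writeSCReference <- function(prior, path) {
  mu <- priorMeans(prior)
  utils::write.table(
    data.frame(gene = rep(rownames(mu), ncol(mu)),
               cell_type = rep(colnames(mu), each = nrow(mu)),
               mean = as.numeric(mu),
               dispersion = rep(priorDispersions(prior), ncol(mu))),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSCReference
#' @export
readSCReference <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  genes <- unique(df$gene)
  types <- unique(df$cell_type)
  mu <- matrix(NA_real_, length(genes), length(types),
               dimnames = list(genes, types))
  mu[cbind(match(df$gene, genes), match(df$cell_type, types))] <- df$mean
  disp <- df$dispersion[match(genes, df$gene)]
  new("SCReference", mean = mu, dispersion = disp)
}

#' Write a ground truth or QC report as TSV
#'
#' Ground truth: long form `gene, cell_type, is_de, logfc, mean_A, mean_B`.
#' QC report: two-column `key, value` pairs.
#'
#' @param gt A [GroundTruth-class].
#' @param report A [QCReport-class].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(gt, path) {
  utils::write.table(
    data.frame(gene = rep(rownames(gt@isDE), ncol(gt@isDE)),
               cell_type = rep(colnames(gt@isDE), each = nrow(gt@isDE)),
               is_de = as.logical(gt@isDE), logfc = as.numeric(gt@logFC),
               mean_A = as.numeric(gt@meanA), mean_B = as.numeric(gt@meanB)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  genes <- unique(df$gene)
  types <- unique(df$cell_type)
  idx <- cbind(match(df$gene, genes), match(df$cell_type, types))
  mk <- function(v, mode = "numeric") {
    m <- matrix(vector(mode, 1), length(genes), length(types),
                dimnames = list(genes, types))
    m[idx] <- v
    m
  }
  new("GroundTruth", isDE = mk(df$is_de, "logical"), logFC = mk(df$logfc),
      meanA = mk(df$mean_A), meanB = mk(df$mean_B))
}

#' @rdname writeGroundTruth
#' @export
writeQCReport <- function(report, path) {
  utils::write.table(
    data.frame(
      key = c("frac_unanalyzable", "logfc_max_mean_dev", "logfc_violations",
              "de_frac_error", "de_count_rel_error", "top100_congruence",
              "passed"),
      value = c(report@fracUnanalyzable, report@logfcMaxMeanDev,
                report@logfcViolations, report@deFracError,
                report@deCountRelError, report@top100Congruence,
                report@passed)),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a tidy results table as TSV
#'
#' @param df A `data.frame` (e.g. from [runExperiment()] or [runDEG()]).
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
writeResultsTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
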