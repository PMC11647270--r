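#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assays colData colData<- rowData
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

## ---------------------------------------------------------------------------
## SimConfig: the validated simulation parameter set
## ---------------------------------------------------------------------------

#' Simulation parameter set
#'
#' A validated bag of all tunable parameters driving the pipeline: the
#' single-cell simulator, the tissue assembler, the artifact models, the DEG
#' tests and the specificity selection. Build one with [simConfig()] or read
#' it from JSON with [loadSimConfig()]. Access entries with `$` or `[[`.
#'
#' @slot params Named (possibly nested) list of parameters.
#' @seealso [simConfig()], [loadSimConfig()], [simConfigDefaults()]
#' @export
setClass("SimConfig", representation(params = "list"))

#' @describeIn SimConfig extract a parameter
#' @param x,name,i object and parameter name
#' @export
setMethod("$", "SimConfig", function(x, name) x@params[[name]])

#' @describeIn SimConfig extract a parameter
#' @export
setMethod("[[", "SimConfig", function(x, i) x@params[[i]])

setMethod("show", "SimConfig", function(object) {
  p <- object@params
  cat("SimConfig:", p$n_genes, "genes x", p$n_cell_types, "cell types,",
      "p_de =", p$p_de, ", logFC =", p$logfc_magnitude, "\n")
  cat("  tissue:", p$n_spots, "spots on a", p$array_rows, "x", p$array_cols,
      "array; seed", p$seed, "\n")
  cat("  leakage: bleed", p$leakage$bleed_rate, ", kernel sd",
      p$leakage$kernel_sd, "; downsample pct", p$downsample$pct, "\n")
  invisible(object)
})

## ---------------------------------------------------------------------------
## SCReference: per-gene, per-cell-type negative binomial prior
## ---------------------------------------------------------------------------

#' Single-cell simulation prior
#'
#' Per-gene, per-cell-type expected counts per cell and per-gene negative
#' binomial dispersions (the `size` parameter of [stats::rnbinom()]); the
#' prior from which two-condition single cells are simulated. Construct with
#' [makeSCPrior()] (synthetic) or [estimatePrior()] (from annotated counts).
#'
#' @slot mean Numeric matrix, genes x cell types, expected counts per cell.
#' @slot dispersion Numeric vector per gene; large values approach Poisson.
#' @export
setClass("SCReference", representation(mean = "matrix", dispersion = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (any(object@mean < 0)) msg <- c(msg, "mean must be >= 0")
    if (length(object@dispersion) != nrow(object@mean))
      msg <- c(msg, "dispersion must have one entry per gene")
    if (any(object@dispersion <= 0)) msg <- c(msg, "dispersion must be > 0")
    if (is.null(rownames(object@mean)) || is.null(colnames(object@mean)))
      msg <- c(msg, "mean must carry gene rownames and cell-type colnames")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "SCReference", function(object) {
  cat("SCReference:", nrow(object@mean), "genes x", ncol(object@mean),
      "cell types\n  mean range [", format(min(object@mean), digits = 3), ",",
      format(max(object@mean), digits = 3), "]\n")
  invisible(object)
})

#' @rdname SCReference-accessors
#' @param x an `SCReference`
#' @return `priorMeans()`: genes x cell types matrix; `priorDispersions()`:
#'   per-gene numeric vector; `cellTypes()`: character vector.
#' @export
priorMeans <- function(x) x@mean

#' @rdname SCReference-accessors
#' @export
priorDispersions <- function(x) x@dispersion

#' Accessors for SCReference objects
#' @name SCReference-accessors
#' @rdname SCReference-accessors
#' @export
cellTypes <- function(x) colnames(x@mean)

## ---------------------------------------------------------------------------
## GroundTruth: the benchmark answer key
## ---------------------------------------------------------------------------

#' Differential-expression ground truth
#'
#' Per (gene, cell type): whether the gene is differentially expressed
#' between conditions, the parameterized log2 fold change, and the two
#' condition means. Invariant: `meanB = meanA * 2^logFC` and `logFC == 0`
#' wherever `isDE` is `FALSE`.
#'
#' @slot isDE Logical matrix, genes x cell types.
#' @slot logFC Numeric matrix (log2 units).
#' @slot meanA,meanB Numeric matrices of per-condition expected counts.
#' @export
setClass("GroundTruth",
  representation(isDE = "matrix", logFC = "matrix",
                 meanA = "matrix", meanB = "matrix"),
  validity = function(object) {
    msg <- NULL
    d <- dim(object@isDE)
    if (!identical(d, dim(object@logFC)) || !identical(d, dim(object@meanA)) ||
        !identical(d, dim(object@meanB)))
      msg <- c(msg, "all matrices must share dimensions")
    if (any(object@logFC[!object@isDE] != 0))
      msg <- c(msg, "logFC must be 0 where isDE is FALSE")
    if (any(abs(object@meanB - object@meanA * 2^object@logFC) >
            1e-8 * (1 + object@meanA)))
      msg <- c(msg, "meanB must equal meanA * 2^logFC")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@isDE), "genes x", ncol(object@isDE),
      "cell types;", sum(object@isDE), "DE flags\n")
  invisible(object)
})

#' @rdname GroundTruth-accessors
#' @param x a `GroundTruth`
#' @export
isDE <- function(x) x@isDE

#' Accessors for GroundTruth objects
#' @name GroundTruth-accessors
#' @rdname GroundTruth-accessors
#' @export
trueLogFC <- function(x) x@logFC

## ---------------------------------------------------------------------------
## QCReport: verdict of the four ground-truth criteria
## ---------------------------------------------------------------------------

#' Ground-truth quality-control report
#'
#' Result of [qcGroundTruth()]. The four criteria: (1) fraction of
#' unanalyzable (gene, cell type) pairs (empirical means zero in both
#' conditions) at most 5%; (2) mean empirical log2FC of the parameterized
#' DEGs within 0.1 of the parameterized value, per cell type and direction;
#' (3) empirically detected DEG fraction (Welch t, p < .01) within 2
#' percentage points of `p_de`; (4) at least 60% of the 100 largest empirical
#' |log2FC| being parameterized DEGs. `passed` is the conjunction.
#'
#' @slot fracUnanalyzable Fraction of pairs with zero means in both conditions.
#' @slot logfcMaxMeanDev Largest |mean empirical - parameterized| log2FC over
#'   (cell type x direction) groups of parameterized DEGs.
#' @slot logfcViolations Count of individual DEGs deviating by more than the
#'   tolerance (diagnostic only; sampling noise makes this nonzero even for a
#'   faithful simulation).
#' @slot deFracError Largest |detected - parameterized| DEG fraction
#'   (percentage points / 100) over the dataset.
#' @slot deCountRelError Relative error of the detected DEG count (diagnostic).
#' @slot top100Congruence Fraction of parameterized DEGs among the top-100
#'   empirical |log2FC| pairs.
#' @slot criteria Named logical vector of the four per-criterion verdicts.
#' @slot passed Logical; all criteria met.
#' @export
setClass("QCReport",
  representation(fracUnanalyzable = "numeric", logfcMaxMeanDev = "numeric",
                 logfcViolations = "integer", deFracError = "numeric",
                 deCountRelError = "numeric", top100Congruence = "numeric",
                 criteria = "logical", passed = "logical"))

setMethod("show", "QCReport", function(object) {
  cat("QCReport:", if (object@passed) "PASSED" else "FAILED", "\n")
  cat(sprintf("  1. unanalyzable fraction     %.4f  [%s]\n",
              object@fracUnanalyzable,
              if (object@criteria[["unanalyzable"]]) "ok" else "FAIL"))
  cat(sprintf("  2. max mean log2FC deviation %.4f  [%s]  (%d per-gene violations)\n",
              object@logfcMaxMeanDev,
              if (object@criteria[["logfc"]]) "ok" else "FAIL",
              object@logfcViolations))
  cat(sprintf("  3. DEG fraction error        %.4f  [%s]\n", object@deFracError,
              if (object@criteria[["de_count"]]) "ok" else "FAIL"))
  cat(sprintf("  4. top-100 congruence        %.4f  [%s]\n",
              object@top100Congruence,
              if (object@criteria[["top100"]]) "ok" else "FAIL"))
  invisible(object)
})

#' @rdname QCReport
#' @param x a `QCReport`
#' @export
qcPassed <- function(x) x@passed

## ---------------------------------------------------------------------------
## TissueLayout: occupied hex positions + condition labels
## ---------------------------------------------------------------------------

#' Tissue layout on a pseudo-hex array
#'
#' Occupied spot positions on a Visium-like array in the doubled-column
#' convention: a position `(row, col)` is valid when `row` and `col` share
#' parity, `0 <= row < arrayRows`, `0 <= col < 2*arrayCols`. Unoccupied
#' positions are background and carry zero transcripts until leakage.
#'
#' @slot arrayRows,arrayCols Array dimensions (rows, spots per row).
#' @slot row,col Integer vectors of occupied positions.
#' @slot condition Factor with levels `A`,`B` per occupied spot (NA before
#'   [assignConditions()]).
#' @export
setClass("TissueLayout",
  representation(arrayRows = "integer", arrayCols = "integer",
                 row = "integer", col = "integer", condition = "factor"),
  validity = function(object) {
    msg <- NULL
    if (length(object@row) != length(object@col))
      msg <- c(msg, "row/col length mismatch")
    if (anyDuplicated(paste(object@row, object@col)))
      msg <- c(msg, "occupied positions must be unique")
    if (!all(hexValid(object@row, object@col, object@arrayRows,
                      object@arrayCols)))
      msg <- c(msg, "positions out of bounds or off-parity")
    if (length(object@condition) &&
        length(object@condition) != length(object@row))
      msg <- c(msg, "condition length mismatch")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "TissueLayout", function(object) {
  cat("TissueLayout:", length(object@row), "occupied spots on",
      object@arrayRows, "x", object@arrayCols, "array")
  if (length(object@condition) && !all(is.na(object@condition)))
    cat(" (A:", sum(object@condition == "A", na.rm = TRUE), "/ B:",
        sum(object@condition == "B", na.rm = TRUE), ")")
  cat("\n")
  invisible(object)
})

#' @rdname TissueLayout
#' @param x a `TissueLayout`
#' @export
nOccupied <- function(x) length(x@row)

## ---------------------------------------------------------------------------
## SpotDataset: spots x genes counts with coordinates and composition
## ---------------------------------------------------------------------------

#' Simulated spot dataset
#'
#' A [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment-class]
#' whose columns are every position of the array (tissue and background).
#' `colData` carries `array_row`, `array_col` (doubled-column convention),
#' `in_tissue`, `condition` (NA for background) and a `composition` matrix
#' column of cells per cell type. `metadata(x)$stage` records the pipeline
#' stage (`ST-M`, `ST-L`, `ST-D`, `ST-LD`). Background spots always have zero
#' composition; they acquire counts only through leakage.
#'
#' @export
setClass("SpotDataset", contains = "SingleCellExperiment",
  validity = function(object) {
    msg <- NULL
    cd <- colData(object)
    need <- c("array_row", "array_col", "in_tissue", "condition", "composition")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
      msg <- c(msg, paste("missing colData columns:", paste(miss, collapse = ", ")))
    if (!"counts" %in% names(assays(object)))
      msg <- c(msg, "missing 'counts' assay")
    else if (min(assay(object, "counts")) < 0)
      msg <- c(msg, "counts must be non-negative")
    if (!length(miss)) {
      comp <- cd$composition
      if (any(comp < 0)) msg <- c(msg, "composition must be non-negative")
      if (any(rowSums(comp[!cd$in_tissue, , drop = FALSE]) > 0))
        msg <- c(msg, "background spots must have zero composition")
    }
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "SpotDataset", function(object) {
  cat("SpotDataset [", metadata(object)$stage %||% "?", "]: ",
      nrow(object), " genes x ", ncol(object), " array positions (",
      sum(colData(object)$in_tissue), " tissue spots)\n", sep = "")
  cat("  total counts:", sum(assay(object, "counts")), "\n")
  invisible(object)
})

#' @rdname SpotDataset-accessors
#' @param x a `SpotDataset`
#' @export
spotCounts <- function(x) assay(x, "counts")

#' @rdname SpotDataset-accessors
#' @export
spotComposition <- function(x) colData(x)$composition

#' @rdname SpotDataset-accessors
#' @export
spotCondition <- function(x) colData(x)$condition

#' @rdname SpotDataset-accessors
#' @export
inTissue <- function(x) colData(x)$in_tissue

#' Accessors for SpotDataset objects
#' @name SpotDataset-accessors
#' @rdname SpotDataset-accessors
#' @export
stageTag <- function(x) metadata(x)$stage

## ---------------------------------------------------------------------------
## STReferenceSummary: target distributions for downsampling calibration
## ---------------------------------------------------------------------------

#' Spatial reference summary distributions
#'
#' Per-gene total counts and per-gene mean expression of a reference spot
#' dataset; the two distributions that [selectDownsamplePct()] matches by
#' two-sample Kolmogorov-Smirnov distance.
#'
#' @slot totals Per-gene total counts.
#' @slot means Per-gene mean expression over tissue spots.
#' @export
setClass("STReferenceSummary",
  representation(totals = "numeric", means = "numeric"),
  validity = function(object) {
    if (length(object@totals) != length(object@means))
      "totals and means must have equal length" else TRUE
  })

setMethod("show", "STReferenceSummary", function(object) {
  cat("STReferenceSummary:", length(object@totals), "genes; median total",
      stats::median(object@totals), "\n")
  invisible(object)
})

## ---------------------------------------------------------------------------
## SpecificityScores: genes x cell types specificity in [0, 1]
## ---------------------------------------------------------------------------

#' Gene-cell specificity scores
#'
#' Genes x cell types matrix of specificity values in `[0, 1]`; for every
#' scored gene the row sums to 1. `metric` records the definition used
#' (`"mean"`: type means scaled by their sum; `"frequency"`: detection rates
#' scaled by their sum). `argmaxType` holds the single cell type each gene is
#' attributed to (ties broken toward the lexicographically smallest type id);
#' genes with a zero denominator are unscored and never selected.
#'
#' @slot score Numeric matrix genes x cell types.
#' @slot metric `"mean"` or `"frequency"`.
#' @slot argmaxType Character vector per gene (NA when unscored).
#' @slot scored Logical vector per gene.
#' @export
setClass("SpecificityScores",
  representation(score = "matrix", metric = "character",
                 argmaxType = "character", scored = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!object@metric %in% c("mean", "frequency"))
      msg <- c(msg, "metric must be 'mean' or 'frequency'")
    s <- object@score[object@scored, , drop = FALSE]
    if (nrow(s) && max(abs(rowSums(s) - 1)) > 1e-8)
      msg <- c(msg, "scored rows must sum to 1")
    if (length(object@argmaxType) != nrow(object@score) ||
        length(object@scored) != nrow(object@score))
      msg <- c(msg, "argmaxType/scored must have one entry per gene")
    if (is.null(msg)) TRUE else msg
  })

setMethod("show", "SpecificityScores", function(object) {
  cat("SpecificityScores [", object@metric, "]: ", nrow(object@score),
      " genes x ", ncol(object@score), " cell types (",
      sum(!object@scored), " unscored)\n", sep = "")
  invisible(object)
})

#' @rdname SpecificityScores
#' @param x a `SpecificityScores`
#' @export
specScores <- function(x) x@score

#' @rdname SpecificityScores
#' @export
argmaxType <- function(x) x@argmaxType
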