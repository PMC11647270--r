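## Synthetic reference generation: an SC prior and ST summary distributions,
## so the whole pipeline is exercisable without any external dataset.

#' Generate a synthetic single-cell prior
#'
#' Draws a per-gene baseline mean from a log-normal, marks a controllable
#' subset of genes as cell-type markers whose mean is multiplied by
#' `marker_fold` in one type, and draws per-gene negative binomial
#' dispersions from a gamma. With `marker_fraction = 0` every cell type has
#' an identical mean vector. All means respect the low-mean filter contract
#' (no gene below `low_mean_cutoff`), so the prior is a valid input to every
#' downstream stage. Defaults produce sparse, overdispersed counts in the
#' dynamic range of droplet data.
#'
#' @param n_genes Number of genes (>= 10).
#' @param n_cell_types Number of cell types (>= 2).
#' @param seed Integer seed.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of the
#'   per-gene baseline mean (counts/cell).
#' @param dispersion_shape,dispersion_scale Gamma parameters of the per-gene
#'   NB size.
#' @param marker_fraction Fraction of genes made type-restricted.
#' @param marker_fold Median multiplicative effect of a marker in its own
#'   type; per-marker folds are drawn log-normally around it
#'   (`marker_fold_sdlog`), since real markers vary in strength — this also
#'   grades the specificity-score distribution instead of making it bimodal.
#' @param marker_fold_sdlog Log-scale SD of the per-marker fold.
#' @param low_mean_cutoff Minimum mean expression (counts/cell).
#' @return An [SCReference-class].
#' @examples
#' prior <- makeSCPrior(100, 3, seed = 1)
#' @export
makeSCPrior <- function(n_genes, n_cell_types, seed,
                        baseline_meanlog = log(0.5), baseline_sdlog = 1.2,
                        dispersion_shape = 2, dispersion_scale = 1,
                        marker_fraction = 0.2, marker_fold = 8,
                        marker_fold_sdlog = 0.8, low_mean_cutoff = 0.005) {
  stopifnot(n_genes >= 10, n_cell_types >= 2,
            marker_fraction >= 0, marker_fraction <= 1, marker_fold >= 1)
  withSeed(seed, {
    base <- pmax(stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog),
                 low_mean_cutoff)
    mu <- matrix(base, n_genes, n_cell_types,
                 dimnames = list(sprintf("gene%04d", seq_len(n_genes)),
                                 sprintf("ct%02d", seq_len(n_cell_types))))
    n_mark <- round(marker_fraction * n_genes)
    if (n_mark > 0) {
      marker_genes <- sample.int(n_genes, n_mark)
      marker_type <- rep_len(seq_len(n_cell_types), n_mark)[sample.int(n_mark)]
      fold <- stats::rlnorm(n_mark, log(marker_fold), marker_fold_sdlog)
      mu[cbind(marker_genes, marker_type)] <-
        mu[cbind(marker_genes, marker_type)] * fold
    }
    disp <- stats::rgamma(n_genes, shape = dispersion_shape,
                          scale = dispersion_scale)
    disp <- pmax(disp, 1e-3)
    new("SCReference", mean = mu, dispersion = disp)
  })
}

#' Build reference summary distributions from a prior
#'
#' Assembles a small tissue from the prior (single-cell simulation at
#' `p_de = 0`, random-walk placement, condition split, cell allocation,
#' aggregation), downsamples it at `target_depth_pct`, and returns the
#' per-gene total-count and mean-expression distributions. Used to test and
#' calibrate Kolmogorov-Smirnov depth selection end to end.
#' `target_depth_pct = 1` returns the full-depth summaries exactly.
#'
#' @param prior An [SCReference-class].
#' @param target_depth_pct Depth in (0, 1].
#' @param seed Integer seed.
#' @param n_spots,array_rows,array_cols Size of the assembled tissue.
#' @return An [STReferenceSummary-class].
#' @export
makeSTReferenceSummaries <- function(prior, target_depth_pct, seed,
                                     n_spots = 80, array_rows = 20,
                                     array_cols = 20) {
  stopifnot(target_depth_pct > 0, target_depth_pct <= 1)
  cfg <- simConfig(
    seed = seed, n_genes = nrow(prior@mean),
    n_cell_types = ncol(prior@mean), p_de = 0,
    n_cells_per_type = as.integer(n_spots * 6),
    n_spots = as.integer(n_spots), array_rows = as.integer(array_rows),
    array_cols = as.integer(array_cols))
  tissue <- buildTissue(prior, cfg, seed = seed, qc = FALSE)
  ds <- tissue$spot
  if (target_depth_pct < 1)
    ds <- downsampleSpots(ds, pct = target_depth_pct,
                          seed = stageSeed(seed, "reference_downsample"))
  spotSummary(ds)
}

#' Summarise a spot dataset into reference distributions
#'
#' @param ds A [SpotDataset-class].
#' @return An [STReferenceSummary-class] with per-gene totals and per-gene
#'   mean expression over tissue spots.
#' @export
spotSummary <- function(ds) {
  m <- spotCounts(ds)[, inTissue(ds), drop = FALSE]
  new("STReferenceSummary",
      totals = as.numeric(Matrix::rowSums(m)),
      means = as.numeric(Matrix::rowMeans(m)))
}
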