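## Spatial artifact models: Gaussian-kernel transcript leakage (ST-L) and
## per-spot depth downsampling (ST-D); applying both yields ST-LD.

#' Gaussian leakage kernel
#'
#' Row-normalized destination weights for transcript leakage. The weight from
#' a source position to every other array position (background included) is
#' `exp(-d^2 / (2 * kernel_sd^2))` with `d` the Euclidean inter-spot distance
#' in spot units; the self-weight is excluded and each row sums to one.
#'
#' @param src_xy Numeric matrix (n_src x 2) of source coordinates.
#' @param dst_xy Numeric matrix (n_dst x 2) of destination coordinates.
#' @param kernel_sd Kernel bandwidth in spot units (> 0).
#' @param self Optional integer vector mapping each source row to its own
#'   column in `dst_xy` (excluded from the kernel).
#' @return n_src x n_dst matrix with rows summing to 1.
#' @export
leakageKernel <- function(src_xy, dst_xy, kernel_sd, self = NULL) {
  stopifnot(kernel_sd > 0)
  d2 <- outer(src_xy[, 1], dst_xy[, 1], "-")^2 +
    outer(src_xy[, 2], dst_xy[, 2], "-")^2
  w <- exp(-d2 / (2 * kernel_sd^2))
  if (!is.null(self)) w[cbind(seq_len(nrow(w)), self)] <- 0
  sw <- rowSums(w)
  stopifnot(all(sw > 0))
  w / sw
}

#' Apply transcript leakage to a spot dataset
#'
#' For every (spot, gene), the number of transcripts leaking out is drawn
#' from Poisson(`bleed_rate * count`), capped at the available count when the
#' draw exceeds it. Leaked transcripts are distributed over destination
#' positions (background included) by multinomial sampling with Gaussian
#' kernel weights. Whenever the cap was triggered for a gene, the
#' destinations of that gene's leaked transcripts are re-sampled with
#' probability proportional to the difference between the counts each spot
#' received and the mean received count, floored at zero. The final count is
#' the remaining plus the received transcripts, so the global transcript
#' total is conserved exactly; `bleed_rate = 0` returns the input unchanged.
#'
#' @param ds A [SpotDataset-class] at stage `ST-M` or `ST-D`.
#' @param bleed_rate Fraction of a spot's transcripts that leave, in `[0, 1]`.
#' @param kernel_sd Gaussian kernel bandwidth in spot units.
#' @param seed Integer seed.
#' @return A [SpotDataset-class] whose stage gains `L`.
#' @export
applyLeakage <- function(ds, bleed_rate = 0.3, kernel_sd = 2, seed = 1) {
  stopifnot(is(ds, "SpotDataset"), bleed_rate >= 0, bleed_rate <= 1)
  stage <- stageTag(ds)
  if (!stage %in% c("ST-M", "ST-D"))
    warning("leakage applied to stage ", stage,
            "; pipeline order is leak-then-downsample")
  out <- ds
  metadata(out)$stage <- switch(stage, "ST-M" = "ST-L", "ST-D" = "ST-LD",
                                paste0(stage, "+L"))
  if (bleed_rate == 0) return(out)

  counts <- spotCounts(ds)
  trip <- Matrix::summary(methods::as(counts, "TsparseMatrix"))
  trip <- trip[trip$x > 0, , drop = FALSE]
  if (!nrow(trip)) return(out)

  withSeed(seed, {
    leak <- stats::rpois(nrow(trip), bleed_rate * trip$x)
    capped_gene <- unique(trip$i[leak > trip$x])
    leak <- pmin(leak, trip$x)

    xy <- hexXY(colData(ds)$array_row, colData(ds)$array_col)
    src_cols <- sort(unique(trip$j[leak > 0]))
    W <- leakageKernel(xy[src_cols, , drop = FALSE], xy, kernel_sd,
                       self = src_cols)

    ## draw destinations per source spot (destination choice is independent
    ## of the gene, so one draw per source covers all its genes)
    rec_i <- rec_j <- integer(0)
    for (s in seq_along(src_cols)) {
      rows <- which(trip$j == src_cols[s] & leak > 0)
      total <- sum(leak[rows])
      if (total == 0) next
      dest <- sample.int(ncol(counts), total, replace = TRUE, prob = W[s, ])
      rec_i <- c(rec_i, rep.int(trip$i[rows], leak[rows]))
      rec_j <- c(rec_j, dest)
    }
    received <- Matrix::sparseMatrix(i = rec_i, j = rec_j, x = 1,
                                     dims = dim(counts))

    ## correction rule: genes whose Poisson draw exceeded an origin count are
    ## re-sampled; destination probability proportional to
    ## max(received - mean received, 0)
    if (length(capped_gene)) {
      logMsg("debug", "leakage cap triggered for ", length(capped_gene),
             " genes; re-sampling destinations")
      for (g in capped_gene) {
        L <- sum(leak[trip$i == g])
        if (L == 0) next
        recv <- received[g, ]
        nz <- recv[recv > 0]
        if (!length(nz)) next
        p <- pmax(recv - mean(nz), 0)
        if (sum(p) == 0) p <- recv
        received[g, ] <- as.numeric(stats::rmultinom(1, L, p))
      }
    }

    leaked_out <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = leak,
                                       dims = dim(counts))
    new_counts <- counts - leaked_out + received
    dimnames(new_counts) <- dimnames(counts)
    SummarizedExperiment::assay(out, "counts") <- new_counts
    out
  })
}

#' Downsample spot transcripts to a target depth
#'
#' Per spot, the post-downsampling total is drawn from
#' Normal(`pct * total`, `sd_frac * pct * total`), rounded and clipped to
#' `[0, total]`; genes are then sampled jointly with probability equal to
#' their original proportions in the spot (multinomial). With
#' `accurate = TRUE` genes are instead sampled without replacement
#' (multivariate hypergeometric), guaranteeing that no (gene, spot) count
#' exceeds the original. All-zero spots remain all-zero.
#'
#' @param ds A [SpotDataset-class].
#' @param pct Target depth fraction in (0, 1].
#' @param accurate Enforce per-gene dominance via sampling without
#'   replacement.
#' @param sd_frac Normal SD as a fraction of the target mean.
#' @param seed Integer seed.
#' @return A [SpotDataset-class] whose stage gains `D`.
#' @export
downsampleSpots <- function(ds, pct, accurate = FALSE, sd_frac = 0.1,
                            seed = 1) {
  stopifnot(is(ds, "SpotDataset"), pct > 0, pct <= 1)
  counts <- methods::as(spotCounts(ds), "CsparseMatrix")
  out <- ds
  stage <- stageTag(ds)
  metadata(out)$stage <- switch(stage, "ST-M" = "ST-D", "ST-L" = "ST-LD",
                                paste0(stage, "+D"))
  withSeed(seed, {
    ptr <- counts@p
    xs <- counts@x
    is_ <- counts@i
    new_x <- numeric(length(xs))
    for (s in seq_len(ncol(counts))) {
      rng <- if (ptr[s + 1L] > ptr[s]) (ptr[s] + 1L):ptr[s + 1L] else integer(0)
      if (!length(rng)) next
      x <- xs[rng]
      total <- sum(x)
      target <- round(stats::rnorm(1, pct * total, sd_frac * pct * total))
      target <- min(max(target, 0), total)
      if (target == 0) { new_x[rng] <- 0; next }
      if (target == total) { new_x[rng] <- x; next }
      if (accurate) {
        drawn <- sample.int(total, target)
        cum <- cumsum(x)
        new_x[rng] <- tabulate(findInterval(drawn - 1, cum) + 1L, length(x))
      } else {
        new_x[rng] <- stats::rmultinom(1, target, x / total)
      }
    }
    counts@x <- new_x
    counts <- Matrix::drop0(counts)
    SummarizedExperiment::assay(out, "counts") <- counts
    out
  })
}

#' Select the downsampling depth by Kolmogorov-Smirnov calibration
#'
#' Downsamples the full-depth dataset at every candidate percentage, computes
#' the per-gene total-count and mean-expression distributions, and measures
#' each against the reference distributions with two-sample KS statistics.
#' The candidate minimizing the sum of the two statistics is returned; ties
#' break toward the larger percentage.
#'
#' @param full A full-depth [SpotDataset-class].
#' @param candidates Candidate depth fractions (default: the seven standard
#'   percentages from [simConfigDefaults()]).
#' @param ref An [STReferenceSummary-class].
#' @param seed Integer seed.
#' @param accurate,sd_frac Passed to [downsampleSpots()].
#' @return The selected depth fraction, with the per-candidate KS sums as the
#'   `"ks"` attribute.
#' @export
selectDownsamplePct <- function(full, candidates = NULL, ref, seed = 1,
                                accurate = FALSE, sd_frac = 0.1) {
  candidates <- candidates %||% simConfigDefaults()$downsample$candidate_pcts
  stopifnot(length(candidates) > 0, is(ref, "STReferenceSummary"))
  ks <- vapply(seq_along(candidates), function(i) {
    d <- downsampleSpots(full, candidates[i], accurate = accurate,
                         sd_frac = sd_frac,
                         seed = stageSeed(seed, paste0("ks", i)))
    s <- spotSummary(d)
    suppressWarnings(
      stats::ks.test(s@totals, ref@totals)$statistic +
        stats::ks.test(s@means, ref@means)$statistic)
  }, numeric(1))
  ord <- order(candidates, decreasing = TRUE)
  best <- ord[1L]
  for (i in ord[-1L]) if (ks[i] < ks[best]) best <- i
  structure(candidates[best], ks = stats::setNames(ks, candidates))
}
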