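## Ground-truth scoring and the experiment runner over configuration grids.

#' Score DEG calls against the ground truth
#'
#' Confusion counts over the evaluated gene set: sensitivity (recall)
#' `TP / (TP + FN)`, specificity `TN / (TN + FP)`, precision
#' `TP / (TP + FP)` and F1 as the harmonic mean of precision and
#' sensitivity. Genes in the evaluated set but absent from `calls` count as
#' non-calls (the p = 1 rule); their ground truth still contributes to
#' FN/TN. A zero denominator yields a score of 0 with `degenerate = TRUE`.
#'
#' @param calls Logical vector of DEG calls, named by gene.
#' @param truth Logical ground-truth DE flags named by gene (one cell type's
#'   column of [isDE()]).
#' @param evaluated Character vector of genes to score over (defaults to
#'   `names(truth)`); for subset analyses pass the subset, so all scores are
#'   relative to it.
#' @return List with `sensitivity`, `specificity`, `precision`, `F1`,
#'   confusion counts and `degenerate`.
#' @examples
#' scoreCalls(c(g1 = TRUE, g2 = FALSE), c(g1 = TRUE, g2 = FALSE))
#' @export
scoreCalls <- function(calls, truth, evaluated = names(truth)) {
  stopifnot(!is.null(names(truth)), all(evaluated %in% names(truth)))
  truth <- truth[evaluated]
  call_vec <- rep(FALSE, length(evaluated))
  names(call_vec) <- evaluated
  known <- intersect(names(calls), evaluated)
  call_vec[known] <- calls[known]
  TP <- sum(call_vec & truth)
  FP <- sum(call_vec & !truth)
  FN <- sum(!call_vec & truth)
  TN <- sum(!call_vec & !truth)
  div <- function(num, den) if (den > 0) num / den else 0
  sens <- div(TP, TP + FN)
  spec <- div(TN, TN + FP)
  prec <- div(TP, TP + FP)
  f1 <- if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  list(sensitivity = sens, specificity = spec, precision = prec, F1 = f1,
       TP = TP, FP = FP, TN = TN, FN = FN,
       degenerate = (TP + FN) == 0 || (TN + FP) == 0 || (TP + FP) == 0)
}

## One stage's DEG run + per-(method, cell type) scoring, as tidy rows.
scoreStage <- function(ds, gt, stage, methods, input_mode, alpha,
                       use_loglib = FALSE) {
  res <- runDEG(ds, methods = methods, input_mode = input_mode,
                alpha = alpha, use_loglib = use_loglib)
  evaluated <- intersect(rownames(ds), rownames(gt@isDE))
  rows <- list()
  for (m in unique(res$method)) {
    for (ct in unique(res$cell_type)) {
      sub <- res[res$method == m & res$cell_type == ct, ]
      calls <- stats::setNames(sub$call, sub$gene)
      truth <- stats::setNames(gt@isDE[, ct], rownames(gt@isDE))
      sc <- scoreCalls(calls, truth, evaluated)
      rows[[paste(stage, m, ct)]] <- data.frame(
        stage = stage, method = m, cell_type = ct,
        sensitivity = sc$sensitivity, specificity = sc$specificity,
        precision = sc$precision, F1 = sc$F1, TP = sc$TP, FP = sc$FP,
        TN = sc$TN, FN = sc$FN, n_evaluated = length(evaluated),
        degenerate = sc$degenerate, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Run a benchmarking experiment over replicates
#'
#' For each replicate: simulate single cells from the prior, QC the ground
#' truth, assemble the tissue (ST-M), derive ST-L (leakage), ST-D
#' (downsampling) and ST-LD (leak then downsample), subsample the
#' single-cell baseline, run the requested DEG methods per cell type on each
#' requested stage, and score every (stage, method, cell type) against the
#' ground truth. A failed replicate is logged and flagged; the run
#' continues.
#'
#' @param config A [SimConfig-class].
#' @param prior Optional [SCReference-class]; default: a synthetic prior
#'   from `config$prior`.
#' @param stages Subset of `c("SC", "ST-M", "ST-L", "ST-D", "ST-LD")`.
#' @param methods DEG methods (see [runDEG()]).
#' @param n_replicates Number of replicate simulations.
#' @param seed Integer seed; replicate r uses substream `(seed, "rep r")`.
#' @param sc_n_cells Cell count of the SC baseline (default: 5000, capped at
#'   the simulated pool).
#' @return Tidy `data.frame`: one row per (replicate, stage, method, cell
#'   type) with all evaluation scores, confusion counts and the QC verdict.
#' @export
runExperiment <- function(config, prior = NULL,
                          stages = c("SC", "ST-M", "ST-L", "ST-D", "ST-LD"),
                          methods = c("ttest", "wilcoxon"),
                          n_replicates = 1, seed = config$seed,
                          sc_n_cells = 5000) {
  stopifnot(all(stages %in% c("SC", "ST-M", "ST-L", "ST-D", "ST-LD")))
  pr <- config$prior
  if (is.null(prior))
    prior <- makeSCPrior(config$n_genes, config$n_cell_types,
                         seed = stageSeed(seed, "prior"),
                         baseline_meanlog = pr$baseline_meanlog,
                         baseline_sdlog = pr$baseline_sdlog,
                         dispersion_shape = pr$dispersion_shape,
                         dispersion_scale = pr$dispersion_scale,
                         marker_fraction = pr$marker_fraction,
                         marker_fold = pr$marker_fold,
                         marker_fold_sdlog = pr$marker_fold_sdlog,
                         low_mean_cutoff = config$low_mean_cutoff)
  alpha <- config$deg$alpha
  input_mode <- config$deg$input_mode
  use_loglib <- isTRUE(config$deg$use_loglib)

  all_rows <- list()
  for (r in seq_len(n_replicates)) {
    rep_seed <- stageSeed(seed, paste0("replicate", r))
    rows <- tryCatch({
      tissue <- buildTissue(prior, config, seed = rep_seed)
      qc_ok <- qcPassed(tissue$qc)
      if (!qc_ok)
        logMsg("warn", "replicate ", r, ": ground-truth QC failed; ",
               "rows flagged")
      datasets <- list()
      stm <- tissue$spot
      if ("ST-M" %in% stages) datasets[["ST-M"]] <- stm
      stl <- if (any(c("ST-L", "ST-LD") %in% stages))
        applyLeakage(stm, bleed_rate = config$leakage$bleed_rate,
                     kernel_sd = config$leakage$kernel_sd,
                     seed = stageSeed(rep_seed, "leakage"))
      if ("ST-L" %in% stages) datasets[["ST-L"]] <- stl
      if ("ST-D" %in% stages)
        datasets[["ST-D"]] <- downsampleSpots(
          stm, pct = config$downsample$pct,
          accurate = config$downsample$accurate,
          sd_frac = config$downsample$sd_frac,
          seed = stageSeed(rep_seed, "downsample"))
      if ("ST-LD" %in% stages)
        datasets[["ST-LD"]] <- downsampleSpots(
          stl, pct = config$downsample$pct,
          accurate = config$downsample$accurate,
          sd_frac = config$downsample$sd_frac,
          seed = stageSeed(rep_seed, "downsample_ld"))

      stage_rows <- list()
      for (nm in names(datasets)) {
        ds <- filterDataset(datasets[[nm]])
        stage_rows[[nm]] <- scoreStage(ds, tissue$gt, nm,
                                       setdiff(methods, NULL), input_mode,
                                       alpha, use_loglib)
      }
      if ("SC" %in% stages) {
        n_sc <- min(sc_n_cells, ncol(tissue$sc))
        sc <- inflateSCBaseline(tissue$sc, n_sc,
                                seed = stageSeed(rep_seed, "inflate"))
        stage_rows[["SC"]] <- scoreStage(sc, tissue$gt, "SC",
                                         setdiff(methods, "lm"), input_mode,
                                         alpha, use_loglib)
      }
      out <- do.call(rbind, stage_rows)
      out$replicate <- r
      out$qc_passed <- qc_ok
      out$failed <- FALSE
      out
    }, error = function(e) {
      logMsg("warn", "replicate ", r, " failed: ", conditionMessage(e))
      data.frame(stage = NA_character_, method = NA_character_,
                 cell_type = NA_character_, sensitivity = NA_real_,
                 specificity = NA_real_, precision = NA_real_, F1 = NA_real_,
                 TP = NA_integer_, FP = NA_integer_, TN = NA_integer_,
                 FN = NA_integer_, n_evaluated = NA_integer_,
                 degenerate = NA, replicate = r, qc_passed = NA,
                 failed = TRUE, stringsAsFactors = FALSE)
    })
    all_rows[[r]] <- rows
  }
  res <- do.call(rbind, all_rows)
  rownames(res) <- NULL
  res
}

#' Summarise an experiment table
#'
#' Mean and SD of every score per (stage, method), plus deltas of the means
#' against a named baseline stage — the presentation used to compare isolated
#' spatial characteristics against the realistic leak-plus-downsample
#' configuration.
#'
#' @param results Table from [runExperiment()].
#' @param baseline_stage Stage to difference against (default `"ST-LD"`).
#' @return `data.frame` with per-(stage, method) means, SDs and deltas.
#' @export
summariseExperiment <- function(results, baseline_stage = "ST-LD") {
  results <- results[!results$failed, , drop = FALSE]
  metrics <- c("sensitivity", "specificity", "precision", "F1")
  agg <- stats::aggregate(results[metrics],
                          by = list(stage = results$stage,
                                    method = results$method), mean)
  sds <- stats::aggregate(results[metrics],
                          by = list(stage = results$stage,
                                    method = results$method), stats::sd)
  names(sds)[-(1:2)] <- paste0(metrics, "_sd")
  out <- merge(agg, sds, by = c("stage", "method"))
  if (baseline_stage %in% out$stage) {
    base <- out[out$stage == baseline_stage, c("method", metrics)]
    names(base)[-1] <- paste0(metrics, "_baseline")
    out <- merge(out, base, by = "method", all.x = TRUE)
    for (m in metrics)
      out[[paste0("delta_", m)]] <- out[[m]] - out[[paste0(m, "_baseline")]]
    out <- out[, !grepl("_baseline$", names(out))]
  }
  out[order(out$stage, out$method), ]
}
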