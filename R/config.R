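## Parameter schema: defaults, validation, JSON round trip.

#' Default simulation parameters
#'
#' The full default parameter set. Probabilities given as scalars
#' (`uniformity_prob`, `density_high_prob`) are recycled across cell types at
#' use time. The seven default downsampling candidate percentages are 10%,
#' 7%, 5%, 3%, 2%, 1% and 0.5% of the original transcripts.
#'
#' @return Named nested list of defaults.
#' @export
simConfigDefaults <- function() {
  list(
    seed = 1L,
    n_genes = 1000L,
    n_cell_types = 5L,
    p_de = 0.1,
    logfc_magnitude = 1,
    n_cells_per_type = 600L,
    n_spots = 300L,
    array_rows = 78L,
    array_cols = 64L,
    uniformity_prob = 0.7,
    density_high_rate = 4,
    density_low_rate = 0.5,
    density_high_prob = 0.5,
    sparse_subset_frac = 0.02,
    low_mean_cutoff = 0.005,
    prior = list(
      baseline_meanlog = log(0.5), baseline_sdlog = 1.2,
      dispersion_shape = 2, dispersion_scale = 1,
      marker_fraction = 0.2, marker_fold = 8, marker_fold_sdlog = 0.8),
    leakage = list(bleed_rate = 0.3, kernel_sd = 2),
    downsample = list(
      candidate_pcts = c(0.10, 0.07, 0.05, 0.03, 0.02, 0.01, 0.005),
      pct = 0.05, accurate = FALSE, sd_frac = 0.1),
    deg = list(alpha = 0.01, input_mode = "containing", use_loglib = FALSE),
    specificity = list(metric = "mean", threshold = 0.3),
    qc = list(logfc_tol = 0.1, max_unanalyzable = 0.05, de_frac_tol = 0.02,
              top100_min = 0.6, de_alpha = 0.01)
  )
}

checkRange <- function(p, key, lo = -Inf, hi = Inf, strict_lo = FALSE,
                       integerish = FALSE) {
  v <- p[[key]]
  bad <- !is.numeric(v) || anyNA(v) ||
    any(if (strict_lo) v <= lo else v < lo) || any(v > hi) ||
    (integerish && any(v != round(v)))
  if (bad) key else NULL
}

validateSimConfig <- function(p) {
  bad <- c(
    checkRange(p, "seed", integerish = TRUE),
    checkRange(p, "n_genes", lo = 1, integerish = TRUE),
    checkRange(p, "n_cell_types", lo = 2, integerish = TRUE),
    checkRange(p, "p_de", lo = 0, hi = 1),
    checkRange(p, "logfc_magnitude", lo = 0, strict_lo = TRUE),
    checkRange(p, "n_cells_per_type", lo = 1, integerish = TRUE),
    checkRange(p, "n_spots", lo = 1, integerish = TRUE),
    checkRange(p, "array_rows", lo = 1, integerish = TRUE),
    checkRange(p, "array_cols", lo = 1, integerish = TRUE),
    checkRange(p, "uniformity_prob", lo = 0, hi = 1),
    checkRange(p, "density_high_rate", lo = 0, strict_lo = TRUE),
    checkRange(p, "density_low_rate", lo = 0, strict_lo = TRUE),
    checkRange(p, "density_high_prob", lo = 0, hi = 1),
    checkRange(p, "sparse_subset_frac", lo = 0, hi = 1),
    checkRange(p, "low_mean_cutoff", lo = 0),
    checkRange(p$leakage, "bleed_rate", lo = 0, hi = 1),
    checkRange(p$leakage, "kernel_sd", lo = 0, strict_lo = TRUE),
    checkRange(p$downsample, "candidate_pcts", lo = 0, hi = 1, strict_lo = TRUE),
    checkRange(p$downsample, "pct", lo = 0, hi = 1, strict_lo = TRUE),
    checkRange(p$downsample, "sd_frac", lo = 0, strict_lo = TRUE),
    checkRange(p$deg, "alpha", lo = 0, hi = 1, strict_lo = TRUE),
    checkRange(p$specificity, "threshold", lo = 0, hi = 1),
    if (!is.logical(p$downsample$accurate)) "accurate" else NULL,
    if (!p$deg$input_mode %in% c("containing", "single", "regional"))
      "input_mode" else NULL,
    if (!p$specificity$metric %in% c("mean", "frequency")) "metric" else NULL
  )
  unknown <- setdiff(names(p), names(simConfigDefaults()))
  if (length(unknown)) bad <- c(bad, paste0("unknown key: ", unknown))
  bad
}

#' Build a simulation configuration
#'
#' Merges the supplied parameters (possibly nested, e.g.
#' `leakage = list(bleed_rate = 0.1)`) into [simConfigDefaults()] and
#' validates the result. Invalid or unknown keys raise an error naming every
#' offending key.
#'
#' @param ... Parameter overrides.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(n_genes = 200, leakage = list(bleed_rate = 0.1))
#' cfg$leakage$bleed_rate
#' @export
simConfig <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  p <- utils::modifyList(simConfigDefaults(), over)
  p$seed <- as.integer(p$seed)
  for (k in c("n_genes", "n_cell_types", "n_cells_per_type", "n_spots",
              "array_rows", "array_cols"))
    p[[k]] <- as.integer(p[[k]])
  bad <- validateSimConfig(p)
  if (length(bad))
    stop("invalid SimConfig parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  new("SimConfig", params = p)
}

#' Read a simulation configuration from JSON
#'
#' Absent optional keys are filled from [simConfigDefaults()]; a minimal file
#' `{"seed": 1}` yields the fully documented default configuration.
#'
#' @param path Path to a JSON file.
#' @return A [SimConfig-class] object.
#' @export
loadSimConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  simConfig(jsonlite::fromJSON(path, simplifyVector = TRUE))
}

#' Write a simulation configuration to JSON
#'
#' @param config A [SimConfig-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSimConfig <- function(config, path) {
  stopifnot(is(config, "SimConfig"))
  jsonlite::write_json(config@params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## Recycle a per-cell-type probability parameter to length k.
perType <- function(v, k) {
  if (length(v) == 1L) rep(v, k)
  else if (length(v) == k) v
  else stop("per-cell-type parameter has length ", length(v),
            " but there are ", k, " cell types", call. = FALSE)
}
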