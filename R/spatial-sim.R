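## Tissue assembly: random-walk spot placement on the pseudo-hex array,
## condition regions, cell allocation under uniformity/density states, and
## aggregation into the mixed (ST-M) spot dataset.

#' Place tissue spots by random walk
#'
#' The first spot is uniform over the array; every subsequent position is the
#' current position plus independent steps of 0, 1 or 2 forward or backward
#' in each axis (row, doubled column). A proposal that is out of bounds,
#' off-parity or already occupied restarts the walk from a randomly chosen
#' occupied position; after 1000 failed trials for one spot an error names
#' the spot index. Once placed, the walk continues from the new spot. The
#' resulting tissues are contiguous blobs with few holes; positions never
#' selected are background.
#'
#' @param n_spots Number of spots; must not exceed `array_rows * array_cols`.
#' @param array_rows,array_cols Array dimensions (rows, spots per row).
#' @param seed Integer seed.
#' @return A [TissueLayout-class] with unassigned conditions.
#' @examples
#' placeSpots(50, 20, 20, seed = 1)
#' @export
placeSpots <- function(n_spots, array_rows, array_cols, seed) {
  n_spots <- as.integer(n_spots)
  array_rows <- as.integer(array_rows)
  array_cols <- as.integer(array_cols)
  if (n_spots > array_rows * array_cols)
    stop("n_spots exceeds array capacity", call. = FALSE)
  withSeed(seed, {
    occ <- matrix(FALSE, array_rows, 2L * array_cols)
    rows <- cols <- integer(n_spots)
    r <- sample.int(array_rows, 1L) - 1L
    c <- 2L * (sample.int(array_cols, 1L) - 1L) + (r %% 2L)
    occ[r + 1L, c + 1L] <- TRUE
    rows[1L] <- r; cols[1L] <- c
    cur_r <- r; cur_c <- c
    for (i in seq_len(n_spots)[-1L]) {
      trials <- 0L
      repeat {
        trials <- trials + 1L
        if (trials > 1000L)
          stop("could not place spot ", i, " within 1000 trials",
               call. = FALSE)
        nr <- cur_r + sample(-2:2, 1L)
        nc <- cur_c + sample(-2:2, 1L)
        ok <- hexValid(nr, nc, array_rows, array_cols) && !occ[nr + 1L, nc + 1L]
        if (ok) {
          occ[nr + 1L, nc + 1L] <- TRUE
          rows[i] <- nr; cols[i] <- nc
          cur_r <- nr; cur_c <- nc
          break
        }
        j <- sample.int(i - 1L, 1L)
        cur_r <- rows[j]; cur_c <- cols[j]
      }
    }
    new("TissueLayout", arrayRows = array_rows, arrayCols = array_cols,
        row = rows, col = cols,
        condition = factor(rep(NA, n_spots), levels = c("A", "B")))
  })
}

## Hex adjacency among a set of positions (logical matrix).
hexAdjacency <- function(row, col) {
  dr <- abs(outer(row, row, "-"))
  dc <- abs(outer(col, col, "-"))
  (dr == 0L & dc == 2L) | (dr == 1L & dc == 1L)
}

#' Split the tissue into two mutually exclusive condition regions
#'
#' Occupied spots are partitioned by a random line through their centroid
#' (labels split at the median projection, so sizes differ by at most one),
#' then repaired toward spatial contiguity: components disconnected from the
#' majority component of their label are flipped, and balance is restored by
#' flipping boundary spots of the larger label. Each region ends contiguous
#' for connected tissues, mimicking diseased samples with adjacent healthy
#' segments.
#'
#' @param layout A [TissueLayout-class] from [placeSpots()].
#' @param seed Integer seed.
#' @return The layout with `condition` filled in.
#' @export
assignConditions <- function(layout, seed) {
  stopifnot(is(layout, "TissueLayout"), nOccupied(layout) > 0)
  n <- nOccupied(layout)
  withSeed(seed, {
    xy <- hexXY(layout@row, layout@col)
    theta <- stats::runif(1, 0, 2 * pi)
    proj <- xy[, 1] * cos(theta) + xy[, 2] * sin(theta)
    ord <- order(proj, layout@row, layout@col)
    cond <- character(n)
    cond[ord[seq_len(ceiling(n / 2))]] <- "A"
    cond[cond == ""] <- "B"
    adj <- hexAdjacency(layout@row, layout@col)

    for (iter in seq_len(50L)) {
      changed <- FALSE
      for (lab in c("A", "B")) {
        idx <- which(cond == lab)
        if (!length(idx)) next
        comp <- hexComponents(layout@row[idx], layout@col[idx])
        if (max(comp) > 1L) {
          main <- which.max(tabulate(comp))
          cond[idx[comp != main]] <- setdiff(c("A", "B"), lab)
          changed <- TRUE
        }
      }
      while (abs(sum(cond == "A") - sum(cond == "B")) > 1L) {
        big <- if (sum(cond == "A") > sum(cond == "B")) "A" else "B"
        small <- setdiff(c("A", "B"), big)
        idx <- which(cond == big)
        nb_other <- vapply(idx, function(i) sum(cond[adj[i, ]] == small),
                           integer(1))
        cand <- idx[nb_other > 0L]
        if (!length(cand)) break
        ## flip the boundary spot most surrounded by the other region
        pick <- cand[which.max(nb_other[nb_other > 0L])]
        cond[pick] <- small
        changed <- TRUE
      }
      if (!changed) break
    }
    layout@condition <- factor(cond, levels = c("A", "B"))
    layout
  })
}

#' Allocate simulated cells to tissue spots
#'
#' Per cell type, a uniformity state is drawn (uniform with probability
#' `uniformity_prob`, else sparse) and a density state (high with probability
#' `density_high_prob`, else low). Uniform types are eligible in every spot
#' of a condition region; sparse types only in a small random subset
#' (`max(3, sparse_subset_frac * region size)` spots). Each eligible spot
#' receives a Poisson(`density rate`) number of cells of that type, filled by
#' sampling without replacement from the single-cell pool of matching type
#' and condition, so every cell in a spot shares the spot's condition.
#'
#' @param sc SingleCellExperiment of simulated cells (from [simulateSC()];
#'   expected to have passed QC).
#' @param layout A condition-labelled [TissueLayout-class].
#' @param config A [SimConfig-class].
#' @param seed Integer seed.
#' @return A `SpotAssignment`: list with `cells` (data.frame of `cell`,
#'   `spot` index into the layout), `composition` (occupied spots x cell
#'   types count matrix) and `states` (per-type uniformity/density draws).
#' @export
allocateCells <- function(sc, layout, config, seed) {
  stopifnot(is(layout, "TissueLayout"), !anyNA(layout@condition))
  ct <- colData(sc)$cell_type
  cond <- as.character(colData(sc)$condition)
  types <- sort(unique(ct))
  k <- length(types)
  uprob <- perType(config$uniformity_prob, k)
  dprob <- perType(config$density_high_prob, k)
  n <- nOccupied(layout)

  withSeed(seed, {
    comp <- matrix(0L, n, k, dimnames = list(NULL, types))
    cell_vec <- character(0)
    spot_vec <- integer(0)
    states <- data.frame(cell_type = types, uniform = NA, high_density = NA)
    for (t in seq_len(k)) {
      uniform <- stats::runif(1) < uprob[t]
      high <- stats::runif(1) < dprob[t]
      rate <- if (high) config$density_high_rate else config$density_low_rate
      states$uniform[t] <- uniform
      states$high_density[t] <- high
      for (cc in c("A", "B")) {
        region <- which(layout@condition == cc)
        if (!length(region)) next
        eligible <- region
        if (!uniform) {
          m <- max(3L, ceiling(config$sparse_subset_frac * length(region)))
          eligible <- region[sample.int(length(region), min(m, length(region)))]
        }
        k_s <- stats::rpois(length(eligible), rate)
        demand <- sum(k_s)
        pool <- which(ct == types[t] & cond == cc)
        if (demand > length(pool))
          stop("cell pool exhausted for type ", types[t], " condition ", cc,
               ": need ", demand, ", have ", length(pool),
               " (shortfall ", demand - length(pool), ")", call. = FALSE)
        chosen <- pool[sample.int(length(pool), demand)]
        spot_idx <- rep(eligible, k_s)
        comp[, t] <- comp[, t] + tabulate(spot_idx, n)
        cell_vec <- c(cell_vec, colnames(sc)[chosen])
        spot_vec <- c(spot_vec, spot_idx)
      }
    }
    structure(list(cells = data.frame(cell = cell_vec, spot = spot_vec,
                                      stringsAsFactors = FALSE),
                   composition = comp, states = states),
              class = "SpotAssignment")
  })
}

#' Aggregate allocated cells into a mixed spot dataset (ST-M)
#'
#' Spot counts are the column-wise sums of the gene-count vectors of the
#' cells assigned to each spot; the total tissue count equals the total count
#' of the allocated cells. Every array position is represented: background
#' positions carry zero counts and zero composition.
#'
#' @param sc SingleCellExperiment of simulated cells.
#' @param assignment A `SpotAssignment` from [allocateCells()].
#' @param layout The matching [TissueLayout-class].
#' @return A [SpotDataset-class] tagged `ST-M`.
#' @export
aggregateCounts <- function(sc, assignment, layout) {
  counts <- assay(sc, "counts")
  n_occ <- nOccupied(layout)
  R <- layout@arrayRows; C <- layout@arrayCols

  ## every valid array position, row-major
  grid_row <- rep(0:(R - 1L), each = C)
  grid_col <- as.integer(2L * (rep(0:(C - 1L), R)) + grid_row %% 2L)
  npos <- length(grid_row)
  pos_key <- paste(grid_row, grid_col)
  occ_at <- match(paste(layout@row, layout@col), pos_key)

  spot_counts <- Matrix::Matrix(0, nrow(counts), npos, sparse = TRUE)
  if (nrow(assignment$cells)) {
    df <- assignment$cells
    agg <- counts[, df$cell, drop = FALSE] %*%
      Matrix::sparseMatrix(i = seq_len(nrow(df)), j = df$spot,
                           x = 1, dims = c(nrow(df), n_occ))
    spot_counts[, occ_at] <- agg
  }
  barcodes <- spotBarcode(grid_row, grid_col)
  dimnames(spot_counts) <- list(rownames(counts), barcodes)

  comp <- matrix(0L, npos, ncol(assignment$composition),
                 dimnames = list(barcodes, colnames(assignment$composition)))
  comp[occ_at, ] <- assignment$composition
  condition <- factor(rep(NA_character_, npos), levels = c("A", "B"))
  condition[occ_at] <- layout@condition
  in_tissue <- logical(npos)
  in_tissue[occ_at] <- TRUE

  cd <- DataFrame(array_row = grid_row, array_col = grid_col,
                  in_tissue = in_tissue, condition = condition,
                  row.names = barcodes)
  cd$composition <- comp
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = spot_counts), colData = cd)
  out <- new("SpotDataset", sce)
  metadata(out)$stage <- "ST-M"
  out
}

#' Assemble a complete tissue from a prior
#'
#' Convenience wrapper chaining [simulateSC()], optional [qcGroundTruth()],
#' [placeSpots()], [assignConditions()], [allocateCells()] and
#' [aggregateCounts()], with stage-specific seed substreams derived from one
#' seed. When the single-cell pool cannot satisfy the Poisson demand of a
#' cell type, the single-cell simulation is re-run with twice as many cells
#' (cells are never reused across spots, which would correlate them).
#'
#' @param prior An [SCReference-class].
#' @param config A [SimConfig-class].
#' @param seed Integer seed (defaults to `config$seed`).
#' @param qc Run ground-truth QC (default `TRUE`).
#' @return List with `spot` ([SpotDataset-class], stage `ST-M`), `sc`, `gt`,
#'   `qc` (a [QCReport-class] or `NULL`), `layout` and `assignment`.
#' @export
buildTissue <- function(prior, config, seed = config$seed, qc = TRUE) {
  layout <- placeSpots(config$n_spots, config$array_rows, config$array_cols,
                       seed = stageSeed(seed, "place_spots"))
  layout <- assignConditions(layout, seed = stageSeed(seed, "conditions"))
  n_cells <- config$n_cells_per_type
  sim <- assignment <- NULL
  for (attempt in 1:4) {
    sim <- simulateSC(prior, config, seed = stageSeed(seed, "sc_sim"),
                      n_cells_per_type = n_cells)
    assignment <- tryCatch(
      allocateCells(sim$sc, layout, config,
                    seed = stageSeed(seed, "allocate")),
      error = function(e) {
        if (!grepl("pool exhausted", conditionMessage(e))) stop(e)
        logMsg("info", "cell pool exhausted; re-simulating with ",
               2L * n_cells, " cells/type/condition")
        NULL
      })
    if (!is.null(assignment)) break
    n_cells <- 2L * n_cells
  }
  if (is.null(assignment))
    stop("cell pool exhausted even after re-simulation", call. = FALSE)
  report <- if (qc) qcGroundTruth(sim$sc, sim$gt, config) else NULL
  spot <- aggregateCounts(sim$sc, assignment, layout)
  list(spot = spot, sc = sim$sc, gt = sim$gt, qc = report,
       layout = layout, assignment = assignment)
}
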