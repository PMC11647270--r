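## Internal helpers: seed substreams, hex-lattice geometry, logging.

#' Derive a stage-specific seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its randomness from a
#' substream derived from the global seed and the stage name, so stages can be
#' re-run in isolation and still reproduce a full-pipeline run.
#'
#' @param seed Global integer seed.
#' @param stage Character stage label (e.g. `"sc_sim"`, `"leakage"`).
#' @return An integer seed below 2^31.
#' @examples
#' stageSeed(1, "sc_sim")
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 10007 + h * 97) %% 2147483629)
}

## Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Pseudo-hex lattice (doubled-column Visium convention).
## A position (r, c) is valid when 0 <= r < nrow, 0 <= c < 2*ncol and
## r and c share parity. Neighbours of (r, c): (r, c+-2), (r+-1, c+-1).
## Euclidean coordinates in spot units: x = c/2, y = r*sqrt(3)/2, so the
## six nearest neighbours all sit at distance 1.
hexXY <- function(row, col) {
  cbind(x = col / 2, y = row * sqrt(3) / 2)
}

hexValid <- function(row, col, array_rows, array_cols) {
  row >= 0 & row < array_rows & col >= 0 & col < 2 * array_cols &
    (row %% 2) == (col %% 2)
}

## Connected components of a set of hex positions under the 6-neighbour rule.
## Returns an integer component label per position. O(n^2) pair scan; the
## tissues handled here have at most a few thousand spots.
hexComponents <- function(row, col) {
  n <- length(row)
  if (n == 0L) return(integer(0))
  lab <- seq_len(n)
  find <- function(i) {
    while (lab[i] != i) {
      lab[i] <<- lab[lab[i]]
      i <- lab[i]
    }
    i
  }
  dr <- abs(outer(row, row, "-"))
  dc <- abs(outer(col, col, "-"))
  adj <- (dr == 0L & dc == 2L) | (dr == 1L & dc == 1L)
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    a <- find(idx[k, 1L]); b <- find(idx[k, 2L])
    if (a != b) lab[a] <- b
  }
  comp <- vapply(seq_len(n), find, integer(1))
  match(comp, unique(comp))
}

spotBarcode <- function(row, col) sprintf("spot_r%03d_c%03d", row, col)

`%||%` <- function(a, b) if (is.null(a)) b else a

logMsg <- function(level = c("info", "debug", "warn"), ...) {
  level <- match.arg(level)
  opt <- getOption("spotbench.log_level", "info")
  rank <- c(debug = 1, info = 2, warn = 3)
  if (rank[[level]] >= rank[[opt]])
    message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"),
                    paste0(..., collapse = "")))
  invisible(NULL)
}
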