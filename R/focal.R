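# Focal (moving-window) statistics via summed-area tables.
# Edge cells use the shrunken in-bounds window: no values are fabricated
# beyond the map edge. Nodata cells contribute nothing to the window; a cell
# that is itself nodata stays nodata in the output.

# 2-D cumulative sum with a leading zero row/col, so window sums come from
# four lookups.
sat <- function(m) {
  s <- apply(m, 2L, cumsum)
  s <- t(apply(s, 1L, cumsum))
  rbind(0, cbind(0, s))
}

window_sums <- function(m, half) {
  nr <- nrow(m); nc <- ncol(m)
  s <- sat(m)
  r0 <- pmax(seq_len(nr) - half, 1L); r1 <- pmin(seq_len(nr) + half, nr)
  c0 <- pmax(seq_len(nc) - half, 1L); c1 <- pmin(seq_len(nc) + half, nc)
  # outer evaluation over all (row, col) windows
  s[r1 + 1L, c1 + 1L, drop = FALSE] - s[r0, c1 + 1L, drop = FALSE] -
    s[r1 + 1L, c0, drop = FALSE] + s[r0, c0, drop = FALSE]
}

check_window <- function(window_cells) {
  if (length(window_cells) != 1L || window_cells < 3L ||
      window_cells %% 2L == 0L) {
    stop_burnsel("`window_cells` must be an odd integer >= 3")
  }
}

#' Focal mean over a centred square window
#'
#' Per-cell mean of the values inside a `window_cells` x `window_cells`
#' window centred on the cell. The habitat analyses use 3x3 (90 m) and 27x27
#' (810 m) windows on 30 m cells.
#'
#' @param grid a `raster_grid`.
#' @param window_cells odd window width in cells (3 or 27 in the standard
#'   pipeline; any odd value >= 3 accepted).
#' @return a `raster_grid` of focal means.
#' @export
focal_mean <- function(grid, window_cells) {
  check_window(window_cells)
  half <- (window_cells - 1L) %/% 2L
  v <- grid$values
  ok <- !is.na(v)
  vz <- v; vz[!ok] <- 0
  sums <- window_sums(vz, half)
  counts <- window_sums(ok + 0, half)
  out <- sums / counts
  out[counts == 0] <- NA
  out[!ok] <- NA
  g <- grid
  g$values <- out
  g$legend <- NULL
  class(g) <- "raster_grid"
  g
}

#' Focal class fraction over a centred square window
#'
#' Fraction of (valid) cells in the window equal to `code`; the standard
#' burn-class and land-cover composition covariates at the two focal scales.
#'
#' @param categorical a `categorical_raster`.
#' @param code class code (or vector of codes pooled together) whose local
#'   fraction is wanted.
#' @param window_cells odd window width in cells.
#' @return a `raster_grid` of fractions in \[0, 1\].
#' @export
focal_fraction <- function(categorical, code, window_cells) {
  check_window(window_cells)
  half <- (window_cells - 1L) %/% 2L
  v <- categorical$values
  ok <- !is.na(v)
  ind <- matrix(as.vector(v) %in% code, nrow(v), ncol(v)) & ok
  hits <- window_sums(ind + 0, half)
  counts <- window_sums(ok + 0, half)
  out <- hits / counts
  out[counts == 0] <- NA
  out[!ok] <- NA
  g <- categorical
  g$values <- out
  g$legend <- NULL
  class(g) <- "raster_grid"
  g
}
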