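#' Spatial occupancy grid of a mouse-day
#'
#' Discretizes the cage into a `rows` (along the 45 cm length) by `cols`
#' (across the 24 cm width) grid and computes the proportion of time spent in
#' each cell. Position between movement events is interpolated by
#' sample-and-hold: the animal is taken to occupy its last recorded position
#' until the next event (and its first recorded position from the window start
#' until the first event). Cells are half-open; a position on a gridline
#' belongs to the higher-index cell.
#'
#' @param rec a [mouse_day()] record with at least one movement event.
#' @param rows,cols grid dimensions; the coarse Home-Base grid is 4 x 2
#'   (8 cells of about 11.2 x 12 cm), the fine density grid 24 x 12
#'   (288 cells).
#' @param geometry a [cage_geometry()].
#' @param restrict_to optional interval set (matrix of `(start, end)` rows,
#'   e.g. the Inactive States of a [state_partition]) to which dwell time is
#'   clipped before normalization.
#' @return a `rows` x `cols` matrix of time proportions summing to 1; linear
#'   cell index of cell `(r, c)` is `(r - 1) * cols + c`.
#' @export
position_occupancy <- function(rec, rows = 4L, cols = 2L,
                               geometry = cage_geometry(),
                               restrict_to = NULL) {
  mv <- rec$movement
  if (nrow(mv) == 0L)
    stop("record has no movement events: position undefined")
  w <- rec$window
  # dwell intervals under sample-and-hold, including hold-back before the
  # first event and hold-forward to the window end
  starts <- c(w[1L], mv$t)
  ends <- c(mv$t, w[2L])
  px <- c(mv$x[1L], mv$x)
  py <- c(mv$y[1L], mv$y)
  keep <- ends > starts
  dwell <- cbind(starts[keep], ends[keep])
  px <- px[keep]; py <- py[keep]
  if (!is.null(restrict_to)) {
    ov <- iv_overlap_matrix(dwell, restrict_to)
    dur <- rowSums(ov)
  } else {
    dur <- dwell[, 2L] - dwell[, 1L]
  }
  cell <- grid_cell_index(px, py, rows, cols, geometry)
  tot <- sum(dur)
  if (tot <= 0) stop("no dwell time in the restricted interval set")
  occ <- matrix(0, rows, cols)
  agg <- tapply(dur, cell, sum)
  idx <- as.integer(names(agg))
  occ[cbind((idx - 1L) %/% cols + 1L, (idx - 1L) %% cols + 1L)] <- agg / tot
  occ
}

#' Designate the Home Base of a mouse-day
#'
#' Computes full-day occupancy on the coarse 4 x 2 grid and applies, in order:
#' (1) if the cell of peak occupancy is the niche cell, the Home Base is the
#' niche cell; (2) otherwise, if the peak cell holds more than half the total
#' time, it is the Home Base; (3) otherwise the Home Base is the edge-adjacent
#' pair of cells with the largest summed occupancy (ties broken by lowest cell
#' indices).
#'
#' @param rec a [mouse_day()] record.
#' @param geometry a [cage_geometry()].
#' @return an object of class `home_base`: list with `cells` (1 or 2 linear
#'   indices in the 4 x 2 grid) and `basis` (`"niche-max"`,
#'   `"single-majority"` or `"contiguous-pair"`).
#' @export
designate_home_base <- function(rec, geometry = cage_geometry()) {
  occ <- position_occupancy(rec, rows = 4L, cols = 2L, geometry = geometry)
  flat <- as.vector(t(occ))          # linear index (r-1)*cols + c
  nc <- niche_cell(geometry)
  peak <- which.max(flat)
  if (peak == nc) {
    hb <- list(cells = nc, basis = "niche-max")
  } else if (flat[peak] > 0.5) {
    hb <- list(cells = peak, basis = "single-majority")
  } else {
    pairs <- adjacent_cell_pairs(rows = 4L, cols = 2L)
    sums <- flat[pairs[, 1L]] + flat[pairs[, 2L]]
    best <- which(sums == max(sums))
    # lowest cell indices on ties
    if (length(best) > 1L)
      best <- best[order(pairs[best, 1L], pairs[best, 2L])][1L]
    hb <- list(cells = as.integer(pairs[best, ]), basis = "contiguous-pair")
  }
  structure(hb, class = "home_base")
}

#' @export
print.home_base <- function(x, ...) {
  cat(sprintf("Home Base: cell(s) %s (%s)\n",
              paste(x$cells, collapse = "+"), x$basis))
  invisible(x)
}

# All edge-adjacent (horizontally or vertically) cell pairs of a rows x cols
# grid, as a matrix of linear index pairs (low, high).
adjacent_cell_pairs <- function(rows, cols) {
  out <- NULL
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    i <- (r - 1L) * cols + c
    if (c < cols) out <- rbind(out, c(i, i + 1L))
    if (r < rows) out <- rbind(out, c(i, i + cols))
  }
  out
}
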