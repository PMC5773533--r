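#' Designate Active and Inactive States
#'
#' Partitions a mouse-day into mutually exclusive Active States (ASs) and
#' Inactive States (ISs). Activity events are the union of all ingestion
#' events (the feeder and water spout are active-behavior sites regardless of
#' Home Base location) and those movement events whose position lies outside
#' the Home Base cell(s) of the coarse 4 x 2 grid. Each event contributes a
#' time interval (movement events are instants, i.e. zero-length intervals);
#' consecutive intervals separated by a gap of at most `ist_s` are bridged,
#' and each maximal bridged run is an AS running from its first event's start
#' to its last event's end. Gaps exceeding `ist_s` -- and the leading/trailing
#' remainders of the window -- are ISs.
#'
#' @param rec a [mouse_day()] record.
#' @param hb a `home_base` from [designate_home_base()].
#' @param ist_s Inactive State Threshold in seconds (default 1200 s = 20 min).
#' @param geometry a [cage_geometry()].
#' @return an object of class `state_partition`: list with `window`, `active`
#'   and `inactive` interval matrices, and `ist_s`. A record with no activity
#'   events yields zero ASs and a single IS covering the window.
#' @export
designate_states <- function(rec, hb, ist_s = 1200,
                             geometry = cage_geometry()) {
  stopifnot(ist_s > 0)
  ev <- activity_event_intervals(rec, hb, geometry)
  w <- rec$window
  if (nrow(ev) == 0L) {
    active <- iv_empty()
  } else {
    active <- iv_union(ev, gap = ist_s)   # gap == IST is bridged
    active <- iv_clip_keep_points(active, w)
  }
  new_state_partition(w, active, ist_s)
}

new_state_partition <- function(window, active, ist_s) {
  inactive <- iv_complement(active, window)
  structure(list(window = as.numeric(window), active = active,
                 inactive = inactive, ist_s = ist_s),
            class = "state_partition")
}

# Clip to the window but keep zero-length rows (lone-event ASs) that lie
# inside it; iv_intersect would drop them.
iv_clip_keep_points <- function(m, window) {
  lo <- pmax(m[, 1L], window[1L]); hi <- pmin(m[, 2L], window[2L])
  keep <- hi >= lo & m[, 1L] < window[2L] & m[, 2L] >= window[1L]
  cbind(lo[keep], hi[keep])
}

activity_event_intervals <- function(rec, hb, geometry) {
  mv <- rec$movement
  parts <- list(iv_empty())
  if (nrow(mv)) {
    cell <- grid_cell_index(mv$x, mv$y, rows = 4L, cols = 2L, geometry)
    outside <- !(cell %in% hb$cells)
    if (any(outside))
      parts <- c(parts, list(cbind(mv$t[outside], mv$t[outside])))
  }
  ing <- rec$ingestion
  if (nrow(ing)) parts <- c(parts, list(cbind(ing$start, ing$end)))
  iv_sort(do.call(rbind, parts))
}

#' @export
print.state_partition <- function(x, ...) {
  cat(sprintf("State partition (IST = %g min): %d Active States (%.1f%% of window), %d Inactive States\n",
              x$ist_s / 60, nrow(x$active),
              100 * iv_length(x$active) / diff(x$window), nrow(x$inactive)))
  invisible(x)
}

#' @export
summary.state_partition <- function(object, ...) {
  dur <- if (nrow(object$active)) (object$active[, 2] - object$active[, 1]) / 60 else numeric(0)
  out <- list(n_as = nrow(object$active),
              as_fraction = iv_length(object$active) / diff(object$window),
              mean_as_min = if (length(dur)) mean(dur) else NA_real_,
              ist_min = object$ist_s / 60)
  class(out) <- "summary.state_partition"
  out
}

#' @export
print.summary.state_partition <- function(x, ...) {
  cat(sprintf("%d ASs, AS fraction %.3f, mean AS duration %.1f min (IST %g min)\n",
              x$n_as, x$as_fraction, x$mean_as_min, x$ist_min))
  invisible(x)
}

#' Brute-force state designation oracle
#'
#' Independent reference implementation of [designate_states()] working on a
#' discrete tick grid: every activity event marks the ticks it covers, runs of
#' marked ticks separated by at most `ist_s` are joined, and each joined run
#' becomes an AS. Exact agreement with the interval-merge parser is guaranteed
#' when all event times fall on the tick grid. Intended for testing.
#'
#' @inheritParams designate_states
#' @param tick_s tick size in seconds (default 1).
#' @return a `state_partition`.
#' @export
states_oracle <- function(rec, hb, ist_s = 1200, tick_s = 1,
                          geometry = cage_geometry()) {
  ev <- activity_event_intervals(rec, hb, geometry)
  w <- rec$window
  if (nrow(ev) == 0L) return(new_state_partition(w, iv_empty(), ist_s))
  n_ticks <- floor(round((w[2L] - w[1L]) / tick_s)) + 1L
  marked <- logical(n_ticks)
  for (i in seq_len(nrow(ev))) {
    a <- ceiling(round((ev[i, 1L] - w[1L]) / tick_s, 9)) + 1L
    b <- floor(round((ev[i, 2L] - w[1L]) / tick_s, 9)) + 1L
    if (b >= a) marked[a:b] <- TRUE
  }
  t_marked <- w[1L] + (which(marked) - 1L) * tick_s
  gaps <- diff(t_marked)
  brk <- which(gaps > ist_s)
  starts <- t_marked[c(1L, brk + 1L)]
  ends <- t_marked[c(brk, length(t_marked))]
  new_state_partition(w, unname(cbind(starts, ends)), ist_s)
}

#' AS counts across a sweep of Inactive State Thresholds
#'
#' Recomputes the state designation at each threshold and reports the number
#' of resulting Active States; counts are non-increasing in the threshold
#' since a larger threshold can only bridge more gaps.
#'
#' @inheritParams designate_states
#' @param ist_values sorted ascending vector of thresholds in seconds.
#' @return data.frame with columns `ist_s` and `n_as`.
#' @export
ist_sweep <- function(rec, hb, ist_values = 60 * seq(5, 60, by = 5),
                      geometry = cage_geometry()) {
  stopifnot(!is.unsorted(ist_values))
  n <- vapply(ist_values, function(ist)
    nrow(designate_states(rec, hb, ist_s = ist, geometry = geometry)$active),
    integer(1))
  data.frame(ist_s = ist_values, n_as = n)
}
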