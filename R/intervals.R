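# Internal half-open interval-set utilities.
#
# An interval set is a numeric matrix with two columns (start, end), rows
# sorted by start, pairwise disjoint, start <= end. Zero-length rows
# (start == end) are permitted: they carry no measure but can mark event
# instants (e.g. a lone movement event seeding an Active State).

iv_empty <- function() matrix(numeric(0), nrow = 0L, ncol = 2L)

iv <- function(start, end) {
  m <- cbind(as.numeric(start), as.numeric(end))
  if (any(m[, 2L] < m[, 1L])) stop("interval end before start")
  iv_sort(m)
}

iv_sort <- function(m) {
  if (nrow(m) > 1L) m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
  m
}

iv_length <- function(m) if (nrow(m) == 0L) 0 else sum(m[, 2L] - m[, 1L])

# Merge rows whose gap to the previous row is <= gap (default 0: touching or
# overlapping rows coalesce). Returns a disjoint sorted set.
iv_union <- function(m, gap = 0) {
  if (nrow(m) <= 1L) return(iv_sort(m))
  m <- iv_sort(m)
  starts <- m[, 1L]; ends <- m[, 2L]
  out_s <- numeric(nrow(m)); out_e <- numeric(nrow(m))
  k <- 1L; out_s[1L] <- starts[1L]; out_e[1L] <- ends[1L]
  for (i in 2L:nrow(m)) {
    if (starts[i] - out_e[k] <= gap) {
      if (ends[i] > out_e[k]) out_e[k] <- ends[i]
    } else {
      k <- k + 1L; out_s[k] <- starts[i]; out_e[k] <- ends[i]
    }
  }
  cbind(out_s[seq_len(k)], out_e[seq_len(k)])
}

# Complement of a disjoint sorted set within a window c(start, end).
iv_complement <- function(m, window) {
  if (nrow(m) == 0L) return(matrix(window, nrow = 1L, ncol = 2L))
  m <- iv_union(m)
  m <- m[m[, 2L] > m[, 1L], , drop = FALSE]  # zero-length rows have no measure
  if (nrow(m) == 0L) return(matrix(window, nrow = 1L, ncol = 2L))
  bounds <- c(window[1L], t(m), window[2L])
  starts <- bounds[seq(1L, length(bounds), by = 2L)]
  ends <- bounds[seq(2L, length(bounds), by = 2L)]
  keep <- ends > starts
  cbind(starts[keep], ends[keep])
}

# Pairwise overlap lengths: rows of a x rows of b.
iv_overlap_matrix <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(matrix(0, nrow(a), nrow(b)))
  lo <- outer(a[, 1L], b[, 1L], pmax)
  hi <- outer(a[, 2L], b[, 2L], pmin)
  ov <- hi - lo
  ov[ov < 0] <- 0
  ov
}

# Intersection of two disjoint sorted sets, as an interval set.
iv_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv_empty())
  lo <- outer(a[, 1L], b[, 1L], pmax)
  hi <- outer(a[, 2L], b[, 2L], pmin)
  keep <- hi > lo
  if (!any(keep)) return(iv_empty())
  iv_sort(cbind(lo[keep], hi[keep]))
}

# a minus b.
iv_setdiff <- function(a, b, window = NULL) {
  if (nrow(a) == 0L) return(iv_empty())
  if (is.null(window)) window <- c(min(a[, 1L]), max(a[, 2L]))
  if (window[1L] >= window[2L]) return(iv_empty())
  iv_intersect(a, iv_complement(b, window))
}

iv_clip <- function(m, window) {
  iv_intersect(m, matrix(window, nrow = 1L))
}

# Total overlap length between two disjoint sets.
iv_overlap_total <- function(a, b) sum(iv_overlap_matrix(a, b))
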