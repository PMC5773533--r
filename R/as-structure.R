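#' Onset- or offset-aligned ingestion probability profile of one mouse-day
#'
#' For every Active State, the 15 min period following its onset (or
#' preceding its offset) is divided into 180 five-second bins; a bin scores 1
#' iff an event of the given behavior overlaps it. Bins beyond the AS extent
#' score 0, and the scoring window is masked to the aligned AS, so events
#' belonging to a neighboring AS are never attributed to a short AS. The
#' mouse-day profile is the mean of the per-AS binary strings.
#'
#' @param rec a [mouse_day()] record.
#' @param partition its [designate_states()] partition (needs at least 1 AS).
#' @param alignment `"onset"` or `"offset"`.
#' @param behavior `"feed"` or `"drink"`.
#' @return numeric vector of 180 probabilities in `[0, 1]`.
#' @export
as_aligned_profile <- function(rec, partition,
                               alignment = c("onset", "offset"),
                               behavior = c("feed", "drink")) {
  alignment <- match.arg(alignment); behavior <- match.arg(behavior)
  as_iv <- partition$active
  if (nrow(as_iv) == 0L) stop("no Active States in this mouse-day")
  ing <- rec$ingestion
  ev <- iv(ing$start[ing$kind == behavior], ing$end[ing$kind == behavior])
  prof <- rowMeans(vapply(seq_len(nrow(as_iv)), function(i)
    aligned_string(ev, as_iv[i, 1L], as_iv[i, 2L], alignment,
                   mask = as_iv[i, , drop = FALSE]),
    numeric(180L)))
  prof
}

# 180-bit string for one anchor. Onset: bin b covers
# [anchor_on + 5 b, anchor_on + 5 (b+1)), b = 0..179; offset: bin b covers
# [anchor_off - 5 (180 - b), anchor_off - 5 (179 - b)), so bin 179 is
# adjacent to the offset. `mask`, when given, restricts scoring to the AS.
aligned_string <- function(ev, on, off, alignment, mask = NULL) {
  if (alignment == "onset") {
    lo <- on + 5 * (0:179)
  } else {
    lo <- off - 5 * (180:1)
  }
  bins <- cbind(lo, lo + 5)
  hit <- if (nrow(ev)) colSums(iv_overlap_matrix(ev, bins) > 0) > 0
         else logical(180L)
  # an event instant boundary: overlap_matrix uses open measure; also catch
  # events that merely touch a bin from inside (zero-length overlap at start)
  if (!is.null(mask)) {
    inside <- bins[, 2L] > mask[1L, 1L] & bins[, 1L] < mask[1L, 2L]
    hit <- hit & inside
  }
  as.numeric(hit)
}

#' Null-model ingestion probability profile
#'
#' Scores 15 min windows exactly as [as_aligned_profile()] does, but anchored
#' at `k` movement events sampled uniformly without replacement instead of at
#' AS boundaries, where `k` is the mouse's mean daily AS count rounded to the
#' nearest integer. No AS masking is applied (the anchors carry no state
#' extent).
#'
#' @inheritParams as_aligned_profile
#' @param k number of anchors (pass the rounded mean daily AS count of the
#'   mouse; defaults to this mouse-day's AS count).
#' @param seed seed for anchor sampling.
#' @return numeric vector of 180 probabilities.
#' @export
null_model_profile <- function(rec, partition,
                               alignment = c("onset", "offset"),
                               behavior = c("feed", "drink"),
                               k = nrow(partition$active), seed = 1) {
  alignment <- match.arg(alignment); behavior <- match.arg(behavior)
  k <- as.integer(round(k))
  if (k < 1) stop("need at least one anchor")
  if (nrow(rec$movement) < k)
    stop("record has fewer movement events than requested anchors")
  ing <- rec$ingestion
  ev <- iv(ing$start[ing$kind == behavior], ing$end[ing$kind == behavior])
  anchors <- with_seed(derive_seed(seed, "null", rec$mouse_id, rec$day),
                       sample(rec$movement$t, k))
  rowMeans(vapply(anchors, function(a)
    aligned_string(ev, a, a, alignment, mask = NULL), numeric(180L)))
}

#' Welch test comparing real and null profile peaks
#'
#' Welch's unequal-variance t-test on per-mouse peak probabilities (the
#' maximum of each mouse's mean profile) between the real aligned profiles
#' and their null-model counterparts.
#'
#' @param real,null numeric vectors of per-mouse peak values (>= 2 each).
#' @return list with `t`, `df` (Welch--Satterthwaite) and two-sided `p`; when
#'   both groups are constant and equal, `t = 0`, `p = 1` by convention.
#' @export
peak_significance <- function(real, null) {
  stopifnot(length(real) >= 2, length(null) >= 2)
  if (stats::sd(real) == 0 && stats::sd(null) == 0) {
    if (isTRUE(all.equal(mean(real), mean(null))))
      return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = Inf * sign(mean(real) - mean(null)), df = NA_real_, p = 0))
  }
  ht <- stats::t.test(real, null, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Mouse-level aligned profiles for a cohort
#'
#' Averages each mouse's mouse-day profiles into one 180-bin profile per
#' mouse, together with the matching null-model profiles (anchored at the
#' mouse's rounded mean daily AS count).
#'
#' @param cohort an [hcm_cohort()].
#' @param partitions named list from [cohort_partitions()].
#' @param alignment,behavior passed to [as_aligned_profile()].
#' @param seed seed for the null anchors.
#' @return list with matrices `real` and `null` (mice x 180) with mouse ids
#'   as rownames, and `strain`, the strain of each row.
#' @export
mouse_profiles <- function(cohort, partitions,
                           alignment = c("onset", "offset"),
                           behavior = c("feed", "drink"), seed = 1) {
  alignment <- match.arg(alignment); behavior <- match.arg(behavior)
  mice <- vapply(cohort$records, `[[`, "", "mouse_id")
  real <- list(); null <- list(); strain <- character(0)
  for (m in unique(mice)) {
    idx <- which(mice == m)
    k <- round(mean(vapply(idx, function(i) {
      key <- paste(m, cohort$records[[i]]$day, sep = "/")
      nrow(partitions[[key]]$active)
    }, 0)))
    prof_r <- NULL; prof_n <- NULL
    for (i in idx) {
      rec <- cohort$records[[i]]
      key <- paste(m, rec$day, sep = "/")
      part <- partitions[[key]]
      if (nrow(part$active) == 0L) next
      prof_r <- rbind(prof_r, as_aligned_profile(rec, part, alignment, behavior))
      prof_n <- rbind(prof_n, null_model_profile(rec, part, alignment,
                                                 behavior, k = max(1, k),
                                                 seed = seed))
    }
    if (is.null(prof_r)) next
    real[[m]] <- colMeans(prof_r)
    null[[m]] <- colMeans(prof_n)
    strain <- c(strain, cohort$records[[idx[1L]]]$strain)
  }
  list(real = do.call(rbind, real), null = do.call(rbind, null),
       strain = strain)
}
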