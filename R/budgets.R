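#' Time budget of one mouse-day
#'
#' Allocates the time of a period among behavior categories. In `"total"`
#' scope the categories are `IS` (Inactive State time), and the within-AS
#' categories `feed`, `drink`, `locomotion` and `other`; in `"AS"` scope the
#' `IS` category is excluded and only Active State time is budgeted.
#' Locomotion time is the summed duration of movement episodes (maximal runs
#' of consecutive movement events with inter-event gaps at most
#' `locomotion_gap_s`). Categories are made disjoint by priority masking
#' (feed over drink over locomotion), so proportions always sum to 1.
#'
#' @param rec a [mouse_day()] record.
#' @param partition its [designate_states()] partition.
#' @param scope `"total"` or `"AS"`.
#' @param period `"24h"`, `"DC"` (dark cycle, ZT 12--24) or `"LC"` (light
#'   cycle, ZT 0--12; 10 h of the 22 h window since maintenance removes
#'   ZT 6--8).
#' @param locomotion_gap_s movement-episode gap parameter in seconds.
#' @return object of class `time_budget`: named proportions plus attributes
#'   `scope` and `period`.
#' @export
compute_time_budget <- function(rec, partition, scope = c("total", "AS"),
                                period = c("24h", "DC", "LC"),
                                locomotion_gap_s = 1) {
  scope <- match.arg(scope); period <- match.arg(period)
  secs <- budget_components(rec, partition, period, locomotion_gap_s)
  if (secs[["period_s"]] <= 0) stop("zero time in period ", period)
  cats <- c("feed", "drink", "locomotion", "other")
  if (scope == "total") {
    p <- c(IS = secs[["IS"]], secs[cats])
    tot <- secs[["period_s"]]
  } else {
    p <- secs[cats]
    tot <- sum(p)
    if (tot <= 0) stop("no Active State time in period ", period)
  }
  structure(p / tot, scope = scope, period = period, class = "time_budget")
}

#' @export
print.time_budget <- function(x, ...) {
  cat(sprintf("%s time budget (%s):\n", attr(x, "scope"), attr(x, "period")))
  print(round(unclass(x), 4))
  invisible(x)
}

# Seconds per category within a period; shared by compute_time_budget and the
# pooled bootstrap.
budget_components <- function(rec, partition, period, locomotion_gap_s = 1) {
  w <- rec$window
  per_iv <- period_intervals(period, w)
  as_p <- iv_intersect(partition$active, per_iv)
  is_s <- iv_overlap_total(partition$inactive, per_iv)
  ing <- rec$ingestion
  feed_iv <- iv_union(iv(ing$start[ing$kind == "feed"],
                         ing$end[ing$kind == "feed"]))
  drink_iv <- iv_union(iv(ing$start[ing$kind == "drink"],
                          ing$end[ing$kind == "drink"]))
  loco_iv <- movement_episodes(rec$movement$t, locomotion_gap_s)
  feed_s <- iv_length(iv_intersect(feed_iv, as_p))
  drink_set <- iv_setdiff(iv_intersect(drink_iv, as_p), feed_iv, w)
  drink_s <- iv_length(drink_set)
  loco_set <- iv_setdiff(iv_setdiff(iv_intersect(loco_iv, as_p), feed_iv, w),
                         drink_iv, w)
  loco_s <- iv_length(loco_set)
  as_s <- iv_length(as_p)
  c(period_s = iv_length(per_iv), IS = is_s, AS = as_s, feed = feed_s,
    drink = drink_s, locomotion = loco_s,
    other = max(0, as_s - feed_s - drink_s - loco_s))
}

period_intervals <- function(period, window) {
  dc <- matrix(c(12, 24) * 3600, nrow = 1L)
  switch(period,
         "24h" = matrix(window, nrow = 1L),
         "DC" = iv_intersect(dc, matrix(window, nrow = 1L)),
         "LC" = iv_setdiff(matrix(window, nrow = 1L), dc, window))
}

# Maximal runs of movement events with inter-event gaps <= gap_s, as
# intervals (single events give zero-length rows and no time).
movement_episodes <- function(t, gap_s) {
  if (length(t) == 0L) return(iv_empty())
  t <- sort(t)
  brk <- which(diff(t) > gap_s)
  starts <- t[c(1L, brk + 1L)]
  ends <- t[c(brk, length(t))]
  cbind(starts, ends)
}

#' Kullback-Leibler divergence between two time budgets
#'
#' `D(P || Q) = sum_c p_c log(p_c / q_c)` in nats, after adding a pseudocount
#' of 1e-6 to every category and renormalizing, so empty categories do not
#' produce infinities. Non-negative; zero iff the smoothed budgets coincide.
#'
#' @param p,q `time_budget` objects (same scope and categories) or plain
#'   probability vectors of equal length.
#' @param eps smoothing pseudocount.
#' @return divergence in nats.
#' @export
kl_divergence <- function(p, q, eps = 1e-6) {
  if (inherits(p, "time_budget") && inherits(q, "time_budget")) {
    if (!identical(attr(p, "scope"), attr(q, "scope")) ||
        !identical(names(p), names(q)))
      stop("budgets have different scope or categories")
  }
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q)) stop("category mismatch")
  p <- (p + eps) / sum(p + eps)
  q <- (q + eps) / sum(q + eps)
  sum(p * log(p / q))
}

#' Bootstrapped dark/light time-budget divergence per strain
#'
#' Per trial, a random half of each mouse's mouse-days is drawn; for each
#' strain the selected mouse-days' category times are pooled into a dark-cycle
#' and a light-cycle budget of the given scope and `KL(DC || LC)` computed.
#' Means and standard deviations over trials are reported per strain.
#'
#' @param cohort an [hcm_cohort()].
#' @param partitions list of `state_partition`s keyed `"<mouse_id>/<day>"`
#'   (computed via [designate_home_base()] + [designate_states()] if `NULL`).
#' @param scope `"total"` or `"AS"`.
#' @param trials bootstrap trials.
#' @param seed seed.
#' @param locomotion_gap_s movement-episode gap parameter.
#' @return data.frame `strain, mean, sd`.
#' @export
dc_lc_divergence_bootstrap <- function(cohort, partitions = NULL,
                                       scope = c("total", "AS"), trials = 20,
                                       seed = 1, locomotion_gap_s = 1) {
  scope <- match.arg(scope)
  if (is.null(partitions)) partitions <- cohort_partitions(cohort)
  # per-MD category seconds for DC and LC, computed once
  comp <- lapply(cohort$records, function(rec) {
    key <- paste(rec$mouse_id, rec$day, sep = "/")
    list(mouse = rec$mouse_id, strain = rec$strain,
         DC = budget_components(rec, partitions[[key]], "DC",
                                locomotion_gap_s),
         LC = budget_components(rec, partitions[[key]], "LC",
                                locomotion_gap_s))
  })
  mice <- vapply(comp, `[[`, "", "mouse")
  strains <- vapply(comp, `[[`, "", "strain")
  cats <- if (scope == "total") c("IS", "feed", "drink", "locomotion", "other")
          else c("feed", "drink", "locomotion", "other")
  per_strain <- sort(unique(strains))
  kls <- with_seed(derive_seed(seed, "klboot", scope), {
    vapply(seq_len(trials), function(tr) {
      take <- unlist(lapply(unique(mice), function(m) {
        idx <- which(mice == m)
        sample(idx, max(1L, floor(length(idx) / 2)))
      }))
      vapply(per_strain, function(s) {
        idx <- intersect(take, which(strains == s))
        dc <- rowSums(vapply(comp[idx], function(x) x$DC[cats],
                             numeric(length(cats))))
        lc <- rowSums(vapply(comp[idx], function(x) x$LC[cats],
                             numeric(length(cats))))
        kl_divergence(dc / sum(dc), lc / sum(lc))
      }, 0)
    }, numeric(length(per_strain)))
  })
  kls <- matrix(kls, nrow = length(per_strain))
  data.frame(strain = per_strain, mean = rowMeans(kls),
             sd = apply(kls, 1, stats::sd))
}

#' Home bases and state partitions for every mouse-day of a cohort
#'
#' @param cohort an [hcm_cohort()].
#' @param ist_s Inactive State Threshold in seconds.
#' @return named list of `state_partition`s keyed `"<mouse_id>/<day>"`.
#' @export
cohort_partitions <- function(cohort, ist_s = 1200) {
  out <- lapply(cohort$records, function(rec) {
    hb <- designate_home_base(rec, cohort$geometry)
    designate_states(rec, hb, ist_s = ist_s, geometry = cohort$geometry)
  })
  names(out) <- vapply(cohort$records,
                       function(r) paste(r$mouse_id, r$day, sep = "/"), "")
  out
}
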