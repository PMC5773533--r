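#' Allocate daily intake totals to individual ingestion events
#'
#' The amount consumed in an event is the proportion of the day's total
#' feeding (or drinking) time taken up by that event, multiplied by the daily
#' total of that kind measured at maintenance.
#'
#' @param rec a [mouse_day()] record.
#' @return data.frame `kind, start, end, amount_g` (one row per ingestion
#'   event, in record order); per kind the amounts sum to the daily total.
#' @export
assign_event_amounts <- function(rec) {
  ing <- rec$ingestion
  out <- cbind(ing, amount_g = rep(0, nrow(ing)))
  for (k in c("feed", "drink")) {
    sel <- ing$kind == k
    tot <- if (k == "feed") rec$food_total_g else rec$water_total_g
    if (!any(sel)) next
    dur <- ing$end[sel] - ing$start[sel]
    if (sum(dur) <= 0)
      stop("total ", k, "ing time is zero but events exist")
    out$amount_g[sel] <- dur / sum(dur) * tot
  }
  out
}

#' The nine circadian feature classes of one mouse-day
#'
#' Computes, per 2 h Zeitgeber bin: food (`F`) and water (`W`) consumed
#' (event amounts prorated by each event's fractional overlap with the bin),
#' distance traveled (`D`; Euclidean step lengths between consecutive
#' movement events, each step assigned to the bin holding the later event),
#' AS probability (`ASP`; fraction of bin time in Active States), AS numbers
#' (`ASN`; ASs whose onset lies in the bin), AS durations (`ASD`; mean full
#' duration in minutes of those ASs, 0 if none), and AS intensities (`ASI_F`,
#' `ASI_W` in g and `ASI_D` in cm per minute of AS time within the bin).
#'
#' @param rec a [mouse_day()] record.
#' @param partition a [designate_states()] partition sharing `rec`'s window.
#' @param amounts output of [assign_event_amounts()] (computed if `NULL`).
#' @param bins bin matrix from [zt_bin_partition()].
#' @return list of nine named 11-vectors, class `day_features`.
#' @export
compute_day_features <- function(rec, partition, amounts = NULL,
                                 bins = zt_bin_partition(rec$window)) {
  if (!isTRUE(all.equal(as.numeric(rec$window),
                        as.numeric(partition$window))))
    stop("record and partition windows differ")
  if (is.null(amounts)) amounts <- assign_event_amounts(rec)
  nb <- nrow(bins)
  bin_len <- bins[, 2L] - bins[, 1L]
  as_iv <- partition$active

  amount_in <- function(kind, target) {
    # grams of `kind` falling in each column-interval of `target`, prorating
    # event amounts by fractional time overlap
    sel <- amounts$kind == kind & (amounts$end > amounts$start)
    if (!any(sel)) return(numeric(ncol_iv(target)))
    ev <- cbind(amounts$start[sel], amounts$end[sel])
    ov <- iv_overlap_matrix(ev, target)
    colSums(ov * (amounts$amount_g[sel] / (ev[, 2L] - ev[, 1L])))
  }
  ncol_iv <- function(m) nrow(m)

  f_bin <- amount_in("feed", bins)
  w_bin <- amount_in("drink", bins)

  # distance: step assigned to the bin containing the later event's timestamp
  mv <- rec$movement
  d_bin <- numeric(nb)
  step_t <- numeric(0); step_d <- numeric(0)
  if (nrow(mv) > 1L) {
    step_d <- sqrt(diff(mv$x)^2 + diff(mv$y)^2)
    step_t <- mv$t[-1L]
    bidx <- findInterval(step_t, bins[, 1L])
    bidx[bidx < 1L | step_t >= bins[nb, 2L]] <- NA
    ok <- !is.na(bidx)
    if (any(ok)) {
      agg <- tapply(step_d[ok], bidx[ok], sum)
      d_bin[as.integer(names(agg))] <- agg
    }
  }

  asp <- as.numeric(colSums(iv_overlap_matrix(as_iv, bins))) / bin_len
  asn <- numeric(nb); asd <- numeric(nb)
  if (nrow(as_iv)) {
    onset_bin <- findInterval(as_iv[, 1L], bins[, 1L])
    onset_bin[as_iv[, 1L] >= bins[nb, 2L]] <- NA
    durations <- (as_iv[, 2L] - as_iv[, 1L]) / 60
    for (b in seq_len(nb)) {
      in_b <- which(onset_bin == b)
      asn[b] <- length(in_b)
      asd[b] <- if (length(in_b)) mean(durations[in_b]) else 0
    }
  }

  # intensities over AS time within each bin
  asi_f <- asi_w <- asi_d <- numeric(nb)
  for (b in seq_len(nb)) {
    asb <- iv_intersect(as_iv, bins[b, , drop = FALSE])
    mins <- iv_length(asb) / 60
    if (mins <= 0) next
    asi_f[b] <- sum(amount_in("feed", asb)) / mins
    asi_w[b] <- sum(amount_in("drink", asb)) / mins
    if (length(step_t)) {
      in_as <- rowSums(outer(step_t, asb[, 1L], ">=") &
                       outer(step_t, asb[, 2L], "<")) > 0
      asi_d[b] <- sum(step_d[in_as]) / mins
    }
  }

  f_bin <- unname(f_bin); w_bin <- unname(w_bin); asp <- unname(asp)
  structure(list(F = f_bin, W = w_bin, D = d_bin, ASP = asp, ASN = asn,
                 ASD = asd, ASI_F = asi_f, ASI_W = asi_w, ASI_D = asi_d),
            class = "day_features")
}

#' @export
print.day_features <- function(x, ...) {
  m <- do.call(rbind, x)
  colnames(m) <- rownames(zt_bin_partition())
  print(round(m, 3))
  invisible(x)
}

#' Feature table for a whole cohort
#'
#' Runs Home-Base designation, state designation and feature extraction on
#' every mouse-day and returns a long table. This is the input to the
#' heritability, classification and clustering analyses.
#'
#' @param cohort an [hcm_cohort()].
#' @param ist_s Inactive State Threshold in seconds.
#' @param home_bases optional list of precomputed `home_base` objects keyed by
#'   `"<mouse_id>/<day>"`.
#' @return data.frame with columns `mouse_id, strain, day, feature, bin,
#'   value` (`bin` in 1..11; `feature` one of F, W, D, ASP, ASN, ASD, ASI_F,
#'   ASI_W, ASI_D).
#' @export
compute_cohort_features <- function(cohort, ist_s = 1200,
                                    home_bases = NULL) {
  bins <- zt_bin_partition()
  rows <- lapply(cohort$records, function(rec) {
    key <- paste(rec$mouse_id, rec$day, sep = "/")
    hb <- if (!is.null(home_bases)) home_bases[[key]]
          else designate_home_base(rec, cohort$geometry)
    part <- designate_states(rec, hb, ist_s = ist_s,
                             geometry = cohort$geometry)
    fe <- compute_day_features(rec, part, bins = bins)
    data.frame(mouse_id = rec$mouse_id, strain = rec$strain, day = rec$day,
               feature = rep(names(fe), each = 11L),
               bin = rep(1:11, length(fe)),
               value = unlist(fe, use.names = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlations between daily patterns of feature classes
#'
#' Aggregates each feature class to its mean 11-bin daily-pattern vector at
#' the requested level and reports Pearson and Spearman correlations between
#' the two members of each pair.
#'
#' @param features long table from [compute_cohort_features()].
#' @param pairs list of length-2 character vectors of feature class names.
#' @param level `"strain"` (one mean vector per strain, correlations pooled
#'   over strains' concatenated vectors) or `"mouse"`.
#' @return data.frame with columns `pair, pearson_r, pearson_p, spearman_rho,
#'   spearman_p, constant` (`constant` flags an undefined correlation from a
#'   zero-variance vector; its statistics are NA).
#' @export
pattern_correlations <- function(features,
                                 pairs = list(c("ASP", "F"), c("ASP", "W"),
                                              c("ASP", "D")),
                                 level = c("strain", "mouse")) {
  level <- match.arg(level)
  grp <- if (level == "strain") features$strain else features$mouse_id
  out <- do.call(rbind, lapply(pairs, function(p) {
    vec <- lapply(p, function(f) {
      sel <- features$feature == f
      agg <- tapply(features$value[sel],
                    list(grp[sel], features$bin[sel]), mean)
      # center each group's pattern so the correlation reflects time-of-day
      # covariation, not between-group level differences
      as.numeric(t(agg - rowMeans(agg)))
    })
    x <- vec[[1L]]; y <- vec[[2L]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      data.frame(pair = paste(p, collapse = "~"), pearson_r = NA_real_,
                 pearson_p = NA_real_, spearman_rho = NA_real_,
                 spearman_p = NA_real_, constant = TRUE)
    } else {
      pe <- stats::cor.test(x, y, method = "pearson")
      sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
      data.frame(pair = paste(p, collapse = "~"),
                 pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
                 spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
                 constant = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Per-mouse-day feature matrix for discrimination analyses
#'
#' Pivots the long feature table into one row per mouse-day, concatenating
#' the requested feature classes (11 columns each, bin order preserved).
#'
#' @param features long table from [compute_cohort_features()].
#' @param classes feature class names to concatenate; the default single
#'   class gives 11-D vectors, all nine give the 99-D combined vectors.
#' @return list with `x` (matrix), `strain`, `mouse`, `day` aligned to rows.
#' @export
feature_matrix <- function(features, classes = "ASP") {
  sel <- features$feature %in% classes
  fe <- features[sel, , drop = FALSE]
  key <- paste(fe$mouse_id, fe$day, sep = "/")
  ukey <- unique(key)
  cols <- paste(rep(classes, each = 11L), rep(1:11, length(classes)),
                sep = ".")
  x <- matrix(NA_real_, length(ukey), length(cols),
              dimnames = list(ukey, cols))
  x[cbind(match(key, ukey),
          match(paste(fe$feature, fe$bin, sep = "."), cols))] <- fe$value
  if (anyNA(x)) stop("incomplete feature table")
  first <- match(ukey, key)
  list(x = x, strain = fe$strain[first], mouse = fe$mouse_id[first],
       day = fe$day[first])
}

#' All pairwise strain clustering scores
#'
#' Runs [pairwise_cluster_accuracy()] for every unordered pair of strains on
#' the given feature class and returns the score table (for 16 strains, the
#' 120 pairwise comparisons).
#'
#' @param features long table from [compute_cohort_features()].
#' @param class feature class name.
#' @param trials,seed passed to [pairwise_cluster_accuracy()].
#' @return data.frame `strain_a, strain_b, train_mean, train_sd, test_mean,
#'   test_sd`.
#' @export
pairwise_strain_scores <- function(features, class = "ASP", trials = 20,
                                   seed = 1) {
  fm <- feature_matrix(features, class)
  strains <- sort(unique(fm$strain))
  out <- NULL
  for (i in seq_along(strains)[-length(strains)]) {
    for (j in (i + 1):length(strains)) {
      sel <- fm$strain %in% strains[c(i, j)]
      res <- pairwise_cluster_accuracy(fm$x[sel, , drop = FALSE],
                                       fm$strain[sel], fm$mouse[sel],
                                       trials = trials,
                                       seed = derive_seed(seed, i, j))
      out <- rbind(out, data.frame(strain_a = strains[i],
                                   strain_b = strains[j],
                                   train_mean = res$train[["mean"]],
                                   train_sd = res$train[["sd"]],
                                   test_mean = res$test[["mean"]],
                                   test_sd = res$test[["sd"]]))
    }
  }
  out
}
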