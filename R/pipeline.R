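#' End-to-end analysis of a cohort
#'
#' Runs the full stage sequence -- Home Base designation, state designation,
#' feature extraction, and the statistical battery (heritability, dark/light
#' budget divergence, within-AS profiles with null-model Welch tests, and
#' optionally pairwise clustering, strain classification and PCA ellipsoids)
#' -- and returns all stage outputs in one report. Deterministic given the
#' cohort and `seed`: every stage draws from a named substream derived from
#' the root seed.
#'
#' @param cohort an [hcm_cohort()].
#' @param ist_s Inactive State Threshold in seconds.
#' @param trials bootstrap trials for the resampled analyses.
#' @param seed root seed.
#' @param n_per_strain balanced group size for heritability (`NULL` skips the
#'   heritability stage when strains are too small).
#' @param classify run the strain classifier and pairwise clustering? (the
#'   costliest stages).
#' @param locomotion_gap_s movement-episode gap for time budgets.
#' @param out_dir optional directory to which stage CSVs are written.
#' @return object of class `analysis_report`.
#' @export
run_full_analysis <- function(cohort, ist_s = 1200, trials = 20, seed = 1,
                              n_per_strain = NULL, classify = TRUE,
                              locomotion_gap_s = 1, out_dir = NULL) {
  report <- list(config = list(ist_s = ist_s, trials = trials, seed = seed,
                               n_per_strain = n_per_strain,
                               locomotion_gap_s = locomotion_gap_s,
                               version = as.character(utils::packageVersion("actistate"))))

  home_bases <- lapply(cohort$records,
                       function(r) designate_home_base(r, cohort$geometry))
  names(home_bases) <- vapply(cohort$records,
                              function(r) paste(r$mouse_id, r$day, sep = "/"),
                              "")
  report$home_bases <- data.frame(
    mouse_id = vapply(cohort$records, `[[`, "", "mouse_id"),
    day = vapply(cohort$records, function(r) r$day, 0L),
    cells = vapply(home_bases, function(h) paste(h$cells, collapse = "+"), ""),
    basis = vapply(home_bases, `[[`, "", "basis"))

  partitions <- lapply(seq_along(cohort$records), function(i)
    designate_states(cohort$records[[i]], home_bases[[i]], ist_s = ist_s,
                     geometry = cohort$geometry))
  names(partitions) <- names(home_bases)
  report$partitions <- partitions

  report$features <- compute_cohort_features(cohort, ist_s = ist_s,
                                             home_bases = home_bases)

  roster <- cohort$roster
  min_mice <- min(table(roster$strain))
  nps <- if (is.null(n_per_strain)) min_mice else n_per_strain
  if (length(unique(roster$strain)) >= 2 && nps >= 2) {
    report$heritability <- list(
      ASP = bootstrap_heritability(report$features, "ASP", trials = trials,
                                   n_per_strain = nps,
                                   seed = derive_seed(seed, "h2", "ASP")),
      D = bootstrap_heritability(report$features, "D", trials = trials,
                                 n_per_strain = nps,
                                 seed = derive_seed(seed, "h2", "D")))
  }

  report$divergence <- list(
    total = dc_lc_divergence_bootstrap(cohort, partitions, "total",
                                       trials = trials,
                                       seed = derive_seed(seed, "kl"),
                                       locomotion_gap_s = locomotion_gap_s),
    AS = dc_lc_divergence_bootstrap(cohort, partitions, "AS",
                                    trials = trials,
                                    seed = derive_seed(seed, "kl"),
                                    locomotion_gap_s = locomotion_gap_s))

  prof <- mouse_profiles(cohort, partitions, "onset", "feed",
                         seed = derive_seed(seed, "prof"))
  prof_off <- mouse_profiles(cohort, partitions, "offset", "drink",
                             seed = derive_seed(seed, "prof"))
  report$profiles <- list(feed_onset = prof, drink_offset = prof_off)
  report$peak_tests <- data.frame(
    test = c("feed_onset", "drink_offset"),
    p = c(peak_significance(apply(prof$real, 1, max),
                            apply(prof$null, 1, max))$p,
          peak_significance(apply(prof_off$real, 1, max),
                            apply(prof_off$null, 1, max))$p))

  if (classify && length(unique(roster$strain)) >= 2) {
    fm <- feature_matrix(report$features,
                         c("F", "W", "D", "ASP", "ASN", "ASD",
                           "ASI_F", "ASI_W", "ASI_D"))
    report$classification <- strain_classifier(
      fm$x, fm$strain, fm$mouse, trials = trials,
      seed = derive_seed(seed, "clf"))
    report$pairwise <- pairwise_strain_scores(report$features, "ASP",
                                              trials = min(trials, 5),
                                              seed = derive_seed(seed, "pair"))
    asp <- feature_matrix(report$features, "ASP")
    mouse_avg <- t(vapply(unique(asp$mouse), function(m)
      colMeans(asp$x[asp$mouse == m, , drop = FALSE]), numeric(11L)))
    if (nrow(mouse_avg) >= 4) {
      model <- pca_projection(mouse_avg)
      strain_of <- asp$strain[match(unique(asp$mouse), asp$mouse)]
      report$pca <- model
      if (min(table(strain_of)) >= 2)
        report$ellipsoids <- strain_ellipsoids(model, strain_of)
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(report$home_bases,
                     file.path(out_dir, "home_bases.csv"), row.names = FALSE)
    utils::write.csv(report$features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    parts <- do.call(rbind, lapply(names(partitions), function(k) {
      p <- partitions[[k]]
      if (!nrow(p$active)) return(NULL)
      data.frame(key = k, state = "AS", start = p$active[, 1],
                 end = p$active[, 2])
    }))
    utils::write.csv(parts, file.path(out_dir, "states.csv"),
                     row.names = FALSE)
  }
  structure(report, class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Active/Inactive State analysis report\n")
  cat(sprintf("  mouse-days: %d; IST %g min; seed %d\n",
              nrow(x$home_bases), x$config$ist_s / 60, x$config$seed))
  if (!is.null(x$heritability))
    cat(sprintf("  daily H2: ASP %.2f, D %.2f\n",
                x$heritability$ASP$mean[["daily"]],
                x$heritability$D$mean[["daily"]]))
  cat(sprintf("  mean DC/LC KL: total %.3f, AS %.3f\n",
              mean(x$divergence$total$mean), mean(x$divergence$AS$mean)))
  if (!is.null(x$classification))
    cat(sprintf("  strain classification: %.1f%% per mouse-day, %.1f%% per mouse\n",
                100 * x$classification$md[["mean"]],
                100 * x$classification$mouse[["mean"]]))
  invisible(x)
}
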