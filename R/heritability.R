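#' Broad-sense heritability from a balanced strain-by-mouse matrix
#'
#' One-way ANOVA variance-component estimate of the fraction of feature
#' variance attributable to strain. With `s` strains of `n` mice each
#' (`N = s n`), per-mouse values `mu_ij` (mouse-day averages), strain means
#' `mu_i` and grand mean `mu`:
#' `MS_between = n / (s - 1) * sum_i (mu - mu_i)^2`,
#' `MS_within = 1 / (N - s) * sum_ij (mu_ij - mu_i)^2`,
#' `V_g = (MS_between - MS_within) / n` (clipped at 0), `V_e = MS_within`,
#' and `H2 = V_g / (V_g + V_e)` (0 when both components vanish).
#'
#' @param m numeric matrix, rows = strains, columns = mice (balanced design;
#'   at least 2 of each).
#' @return list with `H2`, `V_g`, `V_e`, `MS_between`, `MS_within`.
#' @export
broad_sense_heritability <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("unbalanced input: the variance-component formula assumes a complete balanced design")
  s <- nrow(m); n <- ncol(m); N <- s * n
  if (s < 2 || n < 2) stop("need at least 2 strains and 2 mice per strain")
  mu_i <- rowMeans(m)
  mu <- mean(m)
  ms_between <- n / (s - 1) * sum((mu - mu_i)^2)
  ms_within <- sum((m - mu_i)^2) / (N - s)
  v_g <- max(0, (ms_between - ms_within) / n)
  v_e <- ms_within
  h2 <- if (v_g + v_e == 0) 0 else v_g / (v_g + v_e)
  list(H2 = h2, V_g = v_g, V_e = v_e, MS_between = ms_between,
       MS_within = ms_within)
}

#' Bootstrapped heritability of a feature class across bins
#'
#' Per trial: a random half of each mouse's mouse-days (floor of half, at
#' least 1) is drawn without replacement, per-mouse averages recomputed,
#' `n_per_strain` mice subsampled per strain to balance the design, and the
#' variance-component heritability evaluated for each of the 11 bins and for
#' the daily average (mean of the 11 bin values). Means and standard
#' deviations over trials are reported.
#'
#' @param features long table from [compute_cohort_features()].
#' @param feature feature class name (e.g. `"ASP"`).
#' @param trials number of bootstrap trials.
#' @param n_per_strain balanced group size; every strain must have at least
#'   this many mice.
#' @param seed seed controlling all trial resampling.
#' @return list with `mean` and `sd`, named numeric vectors over
#'   `c(bin1..bin11, daily)`, plus `trials` (the trials x 12 matrix of H2
#'   values).
#' @export
bootstrap_heritability <- function(features, feature = "ASP", trials = 20,
                                   n_per_strain = 9, seed = 1) {
  sel <- features$feature == feature
  if (!any(sel)) stop("no rows for feature ", feature)
  fe <- features[sel, , drop = FALSE]
  roster <- unique(fe[c("mouse_id", "strain")])
  per_strain <- table(roster$strain)
  if (any(per_strain < n_per_strain))
    stop("strain(s) with fewer than n_per_strain mice: ",
         paste(names(per_strain)[per_strain < n_per_strain], collapse = ","))
  strains <- sort(unique(roster$strain))
  mouse_days <- split(unique(fe[c("mouse_id", "day")])$day,
                      unique(fe[c("mouse_id", "day")])$mouse_id)
  if (any(vapply(mouse_days, length, 1L) < 2))
    stop("every mouse needs at least 2 mouse-days")
  # value lookup: mouse/day -> 11 bins
  key <- paste(fe$mouse_id, fe$day, sep = "/")
  vals <- tapply(fe$value, list(key, fe$bin), mean)

  h2m <- with_seed(derive_seed(seed, "h2boot"), {
    t(vapply(seq_len(trials), function(tr) {
      # half the MDs per mouse
      mouse_means <- lapply(names(mouse_days), function(m) {
        ds <- mouse_days[[m]]
        take <- sample(ds, max(1L, floor(length(ds) / 2)))
        colMeans(vals[paste(m, take, sep = "/"), , drop = FALSE])
      })
      names(mouse_means) <- names(mouse_days)
      # balance: n_per_strain mice per strain
      h2_tr <- numeric(12L)
      chosen <- unlist(lapply(strains, function(s) {
        mice <- roster$mouse_id[roster$strain == s]
        sample(mice, n_per_strain)
      }))
      for (b in 1:11) {
        m <- matrix(vapply(chosen, function(mm) mouse_means[[mm]][b], 0),
                    nrow = length(strains), ncol = n_per_strain, byrow = TRUE)
        h2_tr[b] <- broad_sense_heritability(m)$H2
      }
      daily <- vapply(chosen, function(mm) mean(mouse_means[[mm]]), 0)
      m <- matrix(daily, nrow = length(strains), ncol = n_per_strain,
                  byrow = TRUE)
      h2_tr[12L] <- broad_sense_heritability(m)$H2
      h2_tr
    }, numeric(12L)))
  })
  colnames(h2m) <- c(paste0("bin", 1:11), "daily")
  list(mean = colMeans(h2m), sd = apply(h2m, 2, stats::sd), trials = h2m)
}
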