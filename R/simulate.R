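#' Strain parameter set for the cohort simulator
#'
#' Describes one strain's circadian Active State (AS) structure: a target AS
#' probability per 2 h bin, mean AS durations, the exponential decay of
#' feeding probability after AS onset, the width of the elevated drinking
#' probability before AS offset, ingestion rates, locomotor speed, and the
#' nest cell.
#'
#' @param strain_id character id.
#' @param asp_profile 11 target AS time fractions in (0, 1), one per
#'   Zeitgeber bin of [zt_bin_partition()].
#' @param mean_as_duration_min mean AS duration per bin (minutes). The default
#'   derives it from `asp_profile` so that the implied mean inactive-state
#'   duration keeps a 1.5x margin over the minimum IS duration.
#' @param feed_onset_decay decay rate (per minute) of the elevated feeding
#'   probability after AS onset; 0 gives time-homogeneous feeding.
#' @param drink_offset_width_s width (seconds) of the elevated drinking
#'   probability before AS offset; 0 disables the offset bump.
#' @param feed_rate_g_per_min,drink_rate_g_per_min intake per minute of
#'   feeding/drinking time (grams).
#' @param speed_cm_per_s characteristic locomotor speed, sets random-walk step
#'   lengths.
#' @param nest_cell linear index of the nest cell in the 4 x 2 grid (default:
#'   the niche cell).
#' @return an object of class `strain_params`.
#' @export
strain_params <- function(strain_id, asp_profile,
                          mean_as_duration_min = NULL,
                          feed_onset_decay = 0.6, drink_offset_width_s = 60,
                          feed_rate_g_per_min = 0.08,
                          drink_rate_g_per_min = 0.04,
                          speed_cm_per_s = 4,
                          nest_cell = niche_cell(cage_geometry())) {
  stopifnot(length(asp_profile) == 11, all(asp_profile > 0),
            all(asp_profile < 1), feed_onset_decay >= 0,
            drink_offset_width_s >= 0, feed_rate_g_per_min > 0,
            drink_rate_g_per_min > 0, speed_cm_per_s > 0)
  if (is.null(mean_as_duration_min)) {
    # E[IS] = E[AS] (1 - f) / f; fixing E[IS] = 2.5 x 21 min gives
    # E[AS] = 2.5 x 21 x f / (1 - f), floored at 2 min. The wide margin
    # keeps inactive pauses well clear of the 15-30 min threshold band, so
    # AS designation is insensitive to the threshold there.
    mean_as_duration_min <- pmax(2, 2.5 * 21 * asp_profile / (1 - asp_profile))
  }
  stopifnot(length(mean_as_duration_min) == 11, all(mean_as_duration_min > 0))
  structure(list(strain_id = as.character(strain_id),
                 asp_profile = as.numeric(asp_profile),
                 mean_as_duration_min = as.numeric(mean_as_duration_min),
                 feed_onset_decay = feed_onset_decay,
                 drink_offset_width_s = drink_offset_width_s,
                 feed_rate_g_per_min = feed_rate_g_per_min,
                 drink_rate_g_per_min = drink_rate_g_per_min,
                 speed_cm_per_s = speed_cm_per_s,
                 nest_cell = as.integer(nest_cell)),
            class = "strain_params")
}

#' Simulation configuration
#'
#' @param strains list of [strain_params()].
#' @param mice_per_strain,days_per_mouse cohort dimensions. The defaults
#'   mirror a typical inbred-strain monitoring design (9 mice per strain, 12
#'   recorded days per mouse).
#' @param seed root seed; all per-mouse-day seeds derive from it.
#' @param min_is_duration_min minimum simulated IS duration (minutes); must
#'   exceed the 20 min Inactive State Threshold so state recovery is exact.
#' @param max_within_as_gap_min cap on within-AS event gaps (minutes); must be
#'   below the threshold.
#' @param time_resolution_s event times are snapped to this grid (seconds).
#' @param event_scale multiplies within-AS movement event density.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(strains, mice_per_strain = 9, days_per_mouse = 12,
                       seed = 1, min_is_duration_min = 21,
                       max_within_as_gap_min = 10, time_resolution_s = 1,
                       event_scale = 1) {
  stopifnot(length(strains) >= 1, mice_per_strain >= 1, days_per_mouse >= 1,
            min_is_duration_min > 20, max_within_as_gap_min < 20,
            time_resolution_s > 0, event_scale > 0)
  structure(list(strains = strains, mice_per_strain = mice_per_strain,
                 days_per_mouse = days_per_mouse, seed = seed,
                 min_is_duration_min = min_is_duration_min,
                 max_within_as_gap_min = max_within_as_gap_min,
                 time_resolution_s = time_resolution_s,
                 event_scale = event_scale),
            class = "sim_config")
}

#' Simulate one mouse-day with ground truth
#'
#' Generates an alternating IS/AS renewal process across the 22 h window. Per
#' bin, AS durations are exponential with the strain's mean and IS durations
#' are the minimum IS duration plus a concentrated gamma component whose mean
#' is chosen so the expected AS time fraction matches the strain's
#' `asp_profile` (and whose shape keeps pauses away from the 15-30 min
#' threshold band, mirroring the robustness of real records there). Within each AS the mouse
#' random-walks outside its nest cell emitting movement events in short
#' locomotor bouts; feeding events occur in 5 s slots with probability
#' decaying exponentially from AS onset and drinking events with a baseline
#' probability plus a bump in the final seconds before AS offset. During ISs
#' the mouse sits in its nest cell (movement events only inside that cell).
#' Daily totals accumulate from per-minute intake rates.
#'
#' @param params a [strain_params()].
#' @param cfg a [sim_config()].
#' @param seed integer seed for this mouse-day.
#' @param mouse_id,day identifiers stored in the record.
#' @return list with `record` (a [mouse_day()]) and `truth` (list with
#'   `active`, the true AS interval matrix, and `nest_cell`).
#' @export
simulate_mouse_day <- function(params, cfg, seed, mouse_id = "m1", day = 1L) {
  w <- standard_window()
  res <- cfg$time_resolution_s
  min_is <- cfg$min_is_duration_min * 60
  e_as <- params$mean_as_duration_min * 60
  f <- params$asp_profile
  # IS = min_is + gamma(shape 6) with mean chosen so the expected AS time
  # fraction per bin equals asp_profile; the concentrated above-minimum
  # component keeps pause durations away from the 15-30 min threshold band
  is_extra_mean <- e_as * (1 - f) / f - min_is
  if (any(is_extra_mean <= 0))
    stop("asp_profile incompatible with the minimum IS duration for bin(s) ",
         paste(which(is_extra_mean <= 0), collapse = ","))
  snap <- function(t) round(t / res) * res
  bin_of <- function(t) pmin(11L, pmax(1L, floor((t - w[1]) / 7200) + 1L))
  with_seed(seed, {
    # --- alternating renewal: true AS intervals ---
    as_iv <- NULL
    t <- w[1]
    repeat {
      b <- bin_of(t)
      t_on <- t + min_is + stats::rgamma(1, shape = 6,
                                         scale = is_extra_mean[b] / 6)
      if (t_on >= w[2] - 120) break
      L <- max(20, stats::rexp(1, 1 / e_as[bin_of(t_on)]))
      t_off <- min(t_on + L, w[2] - res)
      t_on <- snap(t_on); t_off <- snap(t_off)
      if (t_off - t_on < 20) break
      as_iv <- rbind(as_iv, c(t_on, t_off))
      t <- t_off
    }
    if (is.null(as_iv)) as_iv <- iv_empty()

    geometry <- cage_geometry()
    nest <- params$nest_cell
    nest_xy <- cell_center(nest, geometry)

    mv <- list(); ing <- list()
    # --- within-AS events ---
    for (i in seq_len(nrow(as_iv))) {
      a <- as_iv[i, 1]; b2 <- as_iv[i, 2]
      mv[[length(mv) + 1L]] <-
        sim_as_movement(a, b2, params, cfg, geometry, nest)
      ing[[length(ing) + 1L]] <- sim_as_ingestion(a, b2, params)
    }
    # --- IS nest events ---
    is_iv <- iv_complement(as_iv, w)
    for (i in seq_len(nrow(is_iv))) {
      a <- is_iv[i, 1]; b2 <- is_iv[i, 2]
      if (b2 - a < 90) next
      ts <- seq(a + 30, b2 - 30, by = 300)
      ts <- ts[ts >= w[1] & ts < w[2]]
      if (!length(ts)) next
      jit <- matrix(stats::runif(2 * length(ts), -2, 2), ncol = 2)
      mv[[length(mv) + 1L]] <- data.frame(
        t = snap(ts), x = pmin(pmax(nest_xy[1] + jit[, 1], 0.1),
                               geometry$width_cm - 0.1),
        y = pmin(pmax(nest_xy[2] + jit[, 2], 0.1), geometry$length_cm - 0.1))
    }
    movement <- do.call(rbind, mv)
    if (is.null(movement)) movement <- data.frame(t = numeric(0),
                                                  x = numeric(0),
                                                  y = numeric(0))
    movement <- movement[order(movement$t), , drop = FALSE]
    movement <- movement[!duplicated(movement$t), , drop = FALSE]
    ingestion <- do.call(rbind, ing)
    if (is.null(ingestion)) ingestion <- data.frame(kind = character(0),
                                                    start = numeric(0),
                                                    end = numeric(0))
    feed_min <- sum(ingestion$end[ingestion$kind == "feed"] -
                    ingestion$start[ingestion$kind == "feed"]) / 60
    drink_min <- sum(ingestion$end[ingestion$kind == "drink"] -
                     ingestion$start[ingestion$kind == "drink"]) / 60
    rec <- mouse_day(mouse_id = mouse_id, strain = params$strain_id,
                     day = day, movement = movement, ingestion = ingestion,
                     food_total_g = params$feed_rate_g_per_min * feed_min,
                     water_total_g = params$drink_rate_g_per_min * drink_min,
                     window = w, nest_cell = nest)
    list(record = rec, truth = list(active = as_iv, nest_cell = nest))
  })
}

# Movement events within one AS: locomotor bouts of 1 s-spaced events
# separated by short pauses; positions random-walk outside the nest cell.
# The first and last events sit exactly at the AS boundaries.
sim_as_movement <- function(a, b, params, cfg, geometry, nest_cell) {
  times <- a
  t <- a
  bout_mean <- max(2, round(5 * cfg$event_scale))
  repeat {
    n_ev <- 1L + stats::rpois(1, bout_mean)
    bt <- t + seq_len(n_ev)
    bt <- bt[bt < b]
    times <- c(times, bt)
    t <- if (length(bt)) bt[length(bt)] else t
    pause <- min(10 + stats::rexp(1, 1 / 35), cfg$max_within_as_gap_min * 60 - 30)
    t <- t + round(pause)
    if (t >= b) break
    times <- c(times, t)
  }
  times <- unique(c(times, b))
  n <- length(times)
  # random walk starting just outside the nest cell; folded into the cage by
  # reflection, then pushed out of the nest cell by mirroring across its
  # nearest inner edge
  start <- outside_nest_point(nest_cell, geometry)
  if (n > 1) {
    ang <- stats::runif(n - 1, 0, 2 * pi)
    stp <- pmin(pmax(stats::rnorm(n - 1, params$speed_cm_per_s, 1), 1.5), 8)
    x <- fold_into(start[1] + cumsum(stp * cos(ang)), geometry$width_cm)
    y <- fold_into(start[2] + cumsum(stp * sin(ang)), geometry$length_cm)
    out <- push_outside_cell_vec(x, y, nest_cell, geometry)
    x <- c(start[1], out$x); y <- c(start[2], out$y)
  } else {
    x <- start[1]; y <- start[2]
  }
  data.frame(t = times, x = x, y = y)
}

# Reflect coordinates into [0, w] (triangle fold), with a small margin.
fold_into <- function(z, w) {
  z <- z %% (2 * w)
  z <- ifelse(z > w, 2 * w - z, z)
  pmin(pmax(z, 0.05), w - 0.05)
}

# Vectorized variant of push_outside_cell: mirror points inside the cell
# across the nearest inner edge (edges on the cage boundary are not used, so
# the mirror image always stays inside the cage).
push_outside_cell_vec <- function(x, y, cell, geometry) {
  b <- cell_bounds(cell, geometry)
  inside <- x >= b["x0"] & x < b["x1"] & y >= b["y0"] & y < b["y1"]
  if (any(inside)) {
    d <- cbind(if (b["x0"] > 0) x - b["x0"] else Inf,
               if (b["x1"] < geometry$width_cm) b["x1"] - x else Inf,
               if (b["y0"] > 0) y - b["y0"] else Inf,
               if (b["y1"] < geometry$length_cm) b["y1"] - y else Inf)
    pick <- max.col(-d[inside, , drop = FALSE], ties.method = "first")
    xi <- x[inside]; yi <- y[inside]
    xi[pick == 1L] <- 2 * b["x0"] - xi[pick == 1L] - 0.1
    xi[pick == 2L] <- 2 * b["x1"] - xi[pick == 2L] + 0.1
    yi[pick == 3L] <- 2 * b["y0"] - yi[pick == 3L] - 0.1
    yi[pick == 4L] <- 2 * b["y1"] - yi[pick == 4L] + 0.1
    x[inside] <- pmin(pmax(xi, 0.05), geometry$width_cm - 0.05)
    y[inside] <- pmin(pmax(yi, 0.05), geometry$length_cm - 0.05)
  }
  list(x = x, y = y)
}

# Ingestion events within one AS on 5 s slots. Feeding probability decays
# exponentially from onset above a baseline; drinking has a baseline plus a
# bump in the final drink_offset_width_s.
sim_as_ingestion <- function(a, b, params) {
  if (b - a < 10) return(NULL)
  slot <- seq(a, b - 2, by = 5)   # cover the AS up to its offset
  t_min <- (slot - a) / 60
  p_feed <- pmin(0.9, 0.06 + 0.45 * exp(-params$feed_onset_decay * t_min))
  in_bump <- params$drink_offset_width_s > 0 &
    slot >= b - params$drink_offset_width_s - 5
  p_drink <- ifelse(in_bump, 0.55, 0.05)
  take_f <- stats::runif(length(slot)) < p_feed
  take_d <- stats::runif(length(slot)) < p_drink
  out <- NULL
  if (any(take_f)) {
    d <- sample(2:4, sum(take_f), replace = TRUE)
    out <- rbind(out, data.frame(kind = "feed", start = slot[take_f],
                                 end = pmin(slot[take_f] + d, b)))
  }
  if (any(take_d)) {
    out <- rbind(out, data.frame(kind = "drink", start = slot[take_d],
                                 end = pmin(slot[take_d] + 2, b)))
  }
  out
}

cell_center <- function(cell, geometry, rows = 4L, cols = 2L) {
  r <- (cell - 1L) %/% cols + 1L
  c <- (cell - 1L) %% cols + 1L
  c((c - 0.5) * geometry$width_cm / cols,
    (r - 0.5) * geometry$length_cm / rows)
}

cell_bounds <- function(cell, geometry, rows = 4L, cols = 2L) {
  r <- (cell - 1L) %/% cols + 1L
  c <- (cell - 1L) %% cols + 1L
  c(x0 = (c - 1) * geometry$width_cm / cols,
    x1 = c * geometry$width_cm / cols,
    y0 = (r - 1) * geometry$length_cm / rows,
    y1 = r * geometry$length_cm / rows)
}

# A point just outside the nest cell, toward the cage center.
outside_nest_point <- function(cell, geometry) {
  ctr <- c(geometry$width_cm / 2, geometry$length_cm / 2)
  b <- cell_bounds(cell, geometry)
  p <- cell_center(cell, geometry)
  dir <- ctr - p
  if (all(dir == 0)) dir <- c(0, -1)
  dir <- dir / sqrt(sum(dir^2))
  # walk out of the cell bounds plus a margin
  for (k in seq(1, 40, by = 1)) {
    q <- p + k * dir
    if (q[1] < b["x0"] || q[1] > b["x1"] || q[2] < b["y0"] || q[2] > b["y1"])
      return(c(reflect(q[1], 0, geometry$width_cm),
               reflect(q[2], 0, geometry$length_cm)))
  }
  c(geometry$width_cm / 2, geometry$length_cm / 2)
}

reflect <- function(x, lo, hi) {
  if (x < lo) x <- lo + (lo - x)
  if (x > hi) x <- hi - (x - hi)
  min(max(x, lo + 0.05), hi - 0.05)
}

#' Simulate a full cohort with per-mouse-day ground truth
#'
#' @param cfg a [sim_config()].
#' @return list with `cohort` (an [hcm_cohort()]) and `truth`, a list keyed by
#'   `"<mouse_id>/<day>"` holding each mouse-day's true AS intervals and nest
#'   cell.
#' @export
simulate_cohort <- function(cfg) {
  records <- list(); truth <- list()
  for (sp in cfg$strains) {
    for (j in seq_len(cfg$mice_per_strain)) {
      mid <- sprintf("%s_m%02d", sp$strain_id, j)
      for (d in seq_len(cfg$days_per_mouse)) {
        sd <- derive_seed(cfg$seed, sp$strain_id, j, d)
        sim <- simulate_mouse_day(sp, cfg, seed = sd, mouse_id = mid, day = d)
        records[[length(records) + 1L]] <- sim$record
        truth[[paste(mid, d, sep = "/")]] <- sim$truth
      }
    }
  }
  list(cohort = hcm_cohort(records), truth = truth)
}

#' Default library of distinct, nocturnally biased strain parameter sets
#'
#' Builds `n_strains` parameter sets whose AS-probability profiles are
#' nocturnally biased (dark-bin mean above light-bin mean) and pairwise
#' distinct (L2 distance above 0.05), with strain-specific dark-phase peak
#' position, amplitude, width, baseline, ingestion rates and speed.
#'
#' @param n_strains number of strains (2 to 32).
#' @param seed seed for the small jitters applied on top of the deterministic
#'   parameter grids.
#' @return list of [strain_params()].
#' @export
default_strain_library <- function(n_strains = 16, seed = 1) {
  stopifnot(n_strains >= 2, n_strains <= 32)
  with_seed(derive_seed(seed, "library"), {
    bins <- 1:11
    # dark bins are ZT 12-24 = bins 3..8 of the ZT8-start scheme
    out <- vector("list", n_strains)
    for (i in seq_len(n_strains)) {
      peak <- 3.5 + 0.8 * ((i - 1) %% 6)                 # dark-phase peak bin
      amp <- 0.30 + 0.28 * ((5 * (i - 1)) %% n_strains) / max(1, n_strains - 1)
      sig <- 1.0 + 1.2 * ((3 * (i - 1)) %% n_strains) / max(1, n_strains - 1)
      base <- 0.05 + 0.07 * ((7 * (i - 1)) %% n_strains) / max(1, n_strains - 1)
      prof <- base + amp * exp(-((bins - peak)^2) / (2 * sig^2)) +
        stats::runif(11, 0, 0.01)
      prof <- pmin(prof, 0.62)
      out[[i]] <- strain_params(
        strain_id = sprintf("S%02d", i), asp_profile = prof,
        feed_onset_decay = 0.3 + 0.6 * ((i - 1) %% 5) / 4,
        feed_rate_g_per_min = 0.05 + 0.07 * ((9 * (i - 1)) %% n_strains) /
          max(1, n_strains - 1),
        drink_rate_g_per_min = 0.02 + 0.04 * ((11 * (i - 1)) %% n_strains) /
          max(1, n_strains - 1),
        speed_cm_per_s = 2 + 5 * ((13 * (i - 1)) %% n_strains) /
          max(1, n_strains - 1))
    }
    # enforce the documented separation floor
    for (i in seq_len(n_strains - 1)) for (j in (i + 1):n_strains) {
      d <- sqrt(sum((out[[i]]$asp_profile - out[[j]]$asp_profile)^2))
      if (d <= 0.05)
        stop("strain profiles insufficiently separated: ", i, " vs ", j)
    }
    for (sp in out) {
      dark <- mean(sp$asp_profile[3:8]); light <- mean(sp$asp_profile[c(1:2, 9:11)])
      if (dark <= light) stop("profile not nocturnally biased")
    }
    out
  })
}
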