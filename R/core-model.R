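#' Time conventions
#'
#' All times are seconds from Zeitgeber time 0 (ZT0, lights-on) of the calendar
#' day on which a mouse-day starts. The standard observation window runs from
#' the end of the daily maintenance period (ZT8) to its start on the next day
#' (ZT6 + 24 h), i.e. 22 h, excluding maintenance at ZT6--8.
#'
#' @name time-conventions
#' @keywords internal
NULL

ZT_HOUR <- 3600

#' Standard 22 h observation window
#'
#' @return numeric length-2 vector `c(start, end)` in seconds from ZT0
#'   (ZT8 to ZT6 + 24 h).
#' @export
standard_window <- function() c(8 * ZT_HOUR, 30 * ZT_HOUR)

#' Cage geometry
#'
#' Describes the home-cage footprint, the niche (shelter) rectangle and the
#' positions of the feeder and water spout. The coordinate origin is the cage
#' corner nearest the water spout; `x` runs across the cage width, `y` along
#' its length. The niche sits at the far end of the cage from the devices.
#'
#' @param width_cm,length_cm cage footprint in cm.
#' @param niche_rect niche footprint, `c(x0, y0, x1, y1)` in cm. Must lie
#'   inside the cage and inside a single cell of the 2 x 4 occupancy grid.
#' @param feeder_pos,water_pos device coordinates `c(x, y)` in cm.
#' @return an object of class `cage_geometry`.
#' @export
cage_geometry <- function(width_cm = 24, length_cm = 45,
                          niche_rect = c(14, 35, 24, 45),
                          feeder_pos = c(20, 0), water_pos = c(2, 0)) {
  stopifnot(width_cm > 0, length_cm > 0, length(niche_rect) == 4)
  if (niche_rect[1] < 0 || niche_rect[2] < 0 ||
      niche_rect[3] > width_cm || niche_rect[4] > length_cm)
    stop("niche_rect must lie inside the cage rectangle")
  g <- structure(list(width_cm = width_cm, length_cm = length_cm,
                      niche_rect = niche_rect, feeder_pos = feeder_pos,
                      water_pos = water_pos),
                 class = "cage_geometry")
  nc <- niche_cell(g)
  if (length(nc) != 1L)
    stop("niche_rect must be contained in exactly one cell of the 2 x 4 grid")
  g
}

#' @export
print.cage_geometry <- function(x, ...) {
  cat(sprintf("Cage %g x %g cm; niche [%g,%g]x[%g,%g]; niche cell %d of 2x4 grid\n",
              x$width_cm, x$length_cm, x$niche_rect[1], x$niche_rect[3],
              x$niche_rect[2], x$niche_rect[4], niche_cell(x)))
  invisible(x)
}

# Map positions to linear cell indices of a cols-across-width by
# rows-along-length grid. Half-open cells: a position on a gridline belongs to
# the higher-index cell; positions on the far cage edges are clamped into the
# last cell. Linear index = (row - 1) * cols + col, row along y, col along x.
grid_cell_index <- function(x, y, rows, cols, geometry) {
  cx <- pmin(floor(x / (geometry$width_cm / cols)) + 1L, cols)
  cy <- pmin(floor(y / (geometry$length_cm / rows)) + 1L, rows)
  as.integer((cy - 1L) * cols + cx)
}

# The single 2 x 4 grid cell containing the entire niche rectangle; integer(0)
# if it straddles cells.
niche_cell <- function(geometry, rows = 4L, cols = 2L) {
  r <- geometry$niche_rect
  eps <- 1e-9
  corners_x <- c(r[1] + eps, r[3] - eps)
  corners_y <- c(r[2] + eps, r[4] - eps)
  cells <- unique(grid_cell_index(rep(corners_x, each = 2), rep(corners_y, 2),
                                  rows, cols, geometry))
  if (length(cells) == 1L) cells else integer(0)
}

#' Partition the observation window into 11 two-hour Zeitgeber bins
#'
#' The 22 h window is divided into 11 contiguous 2 h bins starting at the
#' window start (ZT 8--10, 10--12, ..., 4--6); the maintenance period ZT 6--8
#' is excluded by construction.
#'
#' @param window observation window `c(start, end)` in seconds from ZT0; must
#'   be 22 h long.
#' @return an 11 x 2 matrix of bin `(start, end)` times in seconds, with
#'   rownames giving the ZT hour ranges.
#' @export
zt_bin_partition <- function(window = standard_window()) {
  if (!isTRUE(all.equal(diff(window), 22 * ZT_HOUR)))
    stop("nonstandard window: the bin scheme is defined for the 22 h window")
  starts <- window[1] + 2 * ZT_HOUR * (0:10)
  bins <- cbind(starts, starts + 2 * ZT_HOUR)
  zt <- (starts / ZT_HOUR) %% 24
  rownames(bins) <- sprintf("%g-%g", zt, zt + 2)
  colnames(bins) <- c("start", "end")
  bins
}

#' Construct a single mouse-day record
#'
#' One mouse-day (MD) bundles the three event types recorded between
#' consecutive maintenance periods: movement events (a timestamp and position,
#' emitted when displacement from the last recorded position exceeds 1 cm),
#' and feeding/drinking events (time intervals), together with the daily food
#' and water totals measured at maintenance.
#'
#' @param mouse_id,strain,day identifiers; `day` is an integer day index.
#' @param movement data.frame with columns `t`, `x`, `y` (seconds, cm).
#' @param ingestion data.frame with columns `kind` ("feed"/"drink"), `start`,
#'   `end` (seconds).
#' @param food_total_g,water_total_g daily totals in grams.
#' @param window observation window `c(start, end)`.
#' @param nest_cell optional observed nest cell index in the 2 x 4 grid.
#' @return an object of class `mouse_day`.
#' @export
mouse_day <- function(mouse_id, strain, day, movement, ingestion,
                      food_total_g = 0, water_total_g = 0,
                      window = standard_window(), nest_cell = NA_integer_) {
  movement <- as.data.frame(movement)[c("t", "x", "y")]
  ingestion <- as.data.frame(ingestion)[c("kind", "start", "end")]
  movement <- movement[order(movement$t), , drop = FALSE]
  ingestion <- ingestion[order(ingestion$start), , drop = FALSE]
  rownames(movement) <- NULL; rownames(ingestion) <- NULL
  structure(list(mouse_id = as.character(mouse_id),
                 strain = as.character(strain), day = as.integer(day),
                 window = as.numeric(window), movement = movement,
                 ingestion = ingestion, food_total_g = as.numeric(food_total_g),
                 water_total_g = as.numeric(water_total_g),
                 nest_cell = as.integer(nest_cell)),
            class = "mouse_day")
}

#' @export
print.mouse_day <- function(x, ...) {
  cat(sprintf("Mouse-day %s (strain %s, day %d): %d movement, %d ingestion events; %.2f g food, %.2f g water\n",
              x$mouse_id, x$strain, x$day, nrow(x$movement), nrow(x$ingestion),
              x$food_total_g, x$water_total_g))
  invisible(x)
}

#' Validate a mouse-day record
#'
#' Checks the structural contract every analysis stage relies on: events
#' sorted in time and inside the observation window, positions inside the
#' cage, same-kind ingestion intervals non-overlapping, non-negative totals,
#' and positive total feeding time whenever feeding events exist.
#'
#' @param rec a [mouse_day()] record.
#' @param geometry a [cage_geometry()].
#' @return a character vector of violation messages; empty iff valid.
#' @export
validate_mouse_day <- function(rec, geometry = cage_geometry()) {
  v <- character(0)
  mv <- rec$movement; ing <- rec$ingestion; w <- rec$window
  if (is.unsorted(mv$t)) v <- c(v, "movement events not sorted by time")
  if (nrow(mv)) {
    out <- mv$x < 0 | mv$x > geometry$width_cm | mv$y < 0 | mv$y > geometry$length_cm
    if (any(out))
      v <- c(v, sprintf("%d movement event(s) outside the cage rectangle", sum(out)))
    if (any(mv$t < w[1] | mv$t >= w[2]))
      v <- c(v, "movement event(s) outside the observation window")
  }
  if (nrow(ing)) {
    if (any(ing$end <= ing$start)) v <- c(v, "ingestion interval with end <= start")
    if (any(ing$start < w[1] | ing$end > w[2]))
      v <- c(v, "ingestion event(s) outside the observation window")
    for (k in unique(ing$kind)) {
      s <- ing[ing$kind == k, , drop = FALSE]
      if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
        v <- c(v, sprintf("overlapping %s intervals", k))
    }
    if (!any(ing$kind %in% c("feed", "drink")))
      v <- c(v, "unknown ingestion kind")
    feed <- ing[ing$kind == "feed", , drop = FALSE]
    if (nrow(feed) && sum(feed$end - feed$start) <= 0)
      v <- c(v, "feeding events present but total feeding time is zero")
  }
  if (rec$food_total_g < 0 || rec$water_total_g < 0)
    v <- c(v, "negative daily total")
  v
}

#' Assemble a cohort of mouse-day records
#'
#' @param records list of [mouse_day()] records; `(mouse_id, day)` pairs must
#'   be unique.
#' @param geometry shared [cage_geometry()].
#' @return an object of class `hcm_cohort` with a strain roster.
#' @export
hcm_cohort <- function(records, geometry = cage_geometry()) {
  ids <- vapply(records, function(r) paste(r$mouse_id, r$day, sep = "\r"), "")
  if (anyDuplicated(ids)) stop("duplicate (mouse_id, day) in cohort")
  mice <- vapply(records, `[[`, "", "mouse_id")
  strains <- vapply(records, `[[`, "", "strain")
  roster <- unique(data.frame(mouse_id = mice, strain = strains,
                              stringsAsFactors = FALSE))
  if (anyDuplicated(roster$mouse_id)) stop("a mouse appears under two strains")
  structure(list(records = records, roster = roster, geometry = geometry),
            class = "hcm_cohort")
}

#' @export
print.hcm_cohort <- function(x, ...) {
  cat(sprintf("Home-cage cohort: %d strains, %d mice, %d mouse-days\n",
              length(unique(x$roster$strain)), nrow(x$roster),
              length(x$records)))
  invisible(x)
}

#' Write a cohort to CSV event tables
#'
#' Writes `events.csv` (`mouse_id,strain,day,kind,t_start,t_end,x,y`; movement
#' rows use `t_start`, `x`, `y`; ingestion rows use `t_start`, `t_end`) and
#' `totals.csv` (`mouse_id,day,food_g,water_g,nest_cell`) to a directory.
#'
#' @param cohort an [hcm_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ev <- do.call(rbind, lapply(cohort$records, function(r) {
    mv <- r$movement; ing <- r$ingestion
    rbind(
      if (nrow(mv)) data.frame(mouse_id = r$mouse_id, strain = r$strain,
                               day = r$day, kind = "move", t_start = mv$t,
                               t_end = NA_real_, x = mv$x, y = mv$y),
      if (nrow(ing)) data.frame(mouse_id = r$mouse_id, strain = r$strain,
                                day = r$day, kind = ing$kind,
                                t_start = ing$start, t_end = ing$end,
                                x = NA_real_, y = NA_real_))
  }))
  tot <- do.call(rbind, lapply(cohort$records, function(r)
    data.frame(mouse_id = r$mouse_id, day = r$day, food_g = r$food_total_g,
               water_g = r$water_total_g, nest_cell = r$nest_cell)))
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(tot, file.path(dir, "totals.csv"), row.names = FALSE,
                   na = "")
  invisible(dir)
}

#' Read a cohort from CSV event tables
#'
#' Reads the dialect written by [write_cohort()] and returns a fully validated
#' cohort; the round trip `read_cohort(write_cohort(x))` reproduces `x` up to
#' float formatting.
#'
#' @param dir directory containing `events.csv` and `totals.csv`.
#' @param geometry a [cage_geometry()].
#' @param window observation window shared by all records.
#' @param validate reject records with a non-empty validation report?
#' @return an [hcm_cohort()].
#' @export
read_cohort <- function(dir, geometry = cage_geometry(),
                        window = standard_window(), validate = TRUE) {
  evf <- file.path(dir, "events.csv"); totf <- file.path(dir, "totals.csv")
  for (f in c(evf, totf)) if (!file.exists(f)) stop("missing file: ", f)
  ev <- utils::read.csv(evf, stringsAsFactors = FALSE)
  need <- c("mouse_id", "strain", "day", "kind", "t_start", "t_end", "x", "y")
  if (!all(need %in% names(ev)))
    stop("events.csv: expected columns ", paste(need, collapse = ","))
  if (any(!ev$kind %in% c("move", "feed", "drink"))) {
    bad <- which(!ev$kind %in% c("move", "feed", "drink"))[1L]
    stop(sprintf("events.csv row %d: unknown kind '%s'", bad, ev$kind[bad]))
  }
  tot <- utils::read.csv(totf, stringsAsFactors = FALSE)
  ev$mouse_id <- as.character(ev$mouse_id)
  tot$mouse_id <- as.character(tot$mouse_id)
  key <- paste(ev$mouse_id, ev$day, sep = "\r")
  tkey <- paste(tot$mouse_id, tot$day, sep = "\r")
  if (anyDuplicated(tkey)) stop("totals.csv: duplicate (mouse_id, day)")
  recs <- lapply(unique(key), function(k) {
    e <- ev[key == k, , drop = FALSE]
    ti <- match(k, tkey)
    if (is.na(ti)) stop("totals.csv: no totals for mouse-day ",
                        sub("\r", " day ", k))
    mv <- e[e$kind == "move", , drop = FALSE]
    ing <- e[e$kind != "move", , drop = FALSE]
    mouse_day(mouse_id = e$mouse_id[1L], strain = e$strain[1L],
              day = e$day[1L],
              movement = data.frame(t = mv$t_start, x = mv$x, y = mv$y),
              ingestion = data.frame(kind = ing$kind, start = ing$t_start,
                                     end = ing$t_end),
              food_total_g = tot$food_g[ti], water_total_g = tot$water_g[ti],
              window = window,
              nest_cell = if ("nest_cell" %in% names(tot)) tot$nest_cell[ti]
                          else NA_integer_)
  })
  if (validate) {
    for (r in recs) {
      v <- validate_mouse_day(r, geometry)
      if (length(v))
        stop(sprintf("invalid mouse-day %s/%d: %s", r$mouse_id, r$day, v[1L]))
    }
  }
  hcm_cohort(recs, geometry)
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a bounded child seed from a root seed and a label (deterministic,
# below 2^31).
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147480009
  as.integer(h)
}
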