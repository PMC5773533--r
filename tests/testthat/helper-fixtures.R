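# Shared fixtures, built in code and cached for the duration of one test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# A hand-built record: events at chosen times/positions, defaults inside the
# standard window. Positions default to the open field (outside every cell of
# the top row, i.e. far from the default niche cell 8).
make_record <- function(move_t = numeric(0), move_x = 5, move_y = 10,
                        feed = NULL, drink = NULL,
                        food_g = 0, water_g = 0,
                        mouse_id = "t1", strain = "TST", day = 1L) {
  n <- length(move_t)
  movement <- data.frame(t = move_t,
                         x = rep_len(move_x, n), y = rep_len(move_y, n))
  ingestion <- rbind(
    if (!is.null(feed)) data.frame(kind = "feed", start = feed[, 1],
                                   end = feed[, 2]),
    if (!is.null(drink)) data.frame(kind = "drink", start = drink[, 1],
                                    end = drink[, 2]))
  if (is.null(ingestion))
    ingestion <- data.frame(kind = character(0), start = numeric(0),
                            end = numeric(0))
  mouse_day(mouse_id, strain, day, movement, ingestion,
            food_total_g = food_g, water_total_g = water_g)
}

# Home base fixed at the niche cell, for hand-built records.
niche_home_base <- function() {
  structure(list(cells = actistate:::niche_cell(cage_geometry()),
                 basis = "niche-max"), class = "home_base")
}

# Small default-structure cohort: 2 strains x 3 mice x 3 days.
mini_sim <- function() fixture("mini_sim", function() {
  lib <- default_strain_library(2, seed = 42)
  simulate_cohort(sim_config(lib, mice_per_strain = 3, days_per_mouse = 3,
                             seed = 101))
})

# Larger 16-strain cohort shared by the discrimination/heritability checks.
big_sim <- function() fixture("big_sim", function() {
  lib <- default_strain_library(16, seed = 3)
  simulate_cohort(sim_config(lib, mice_per_strain = 6, days_per_mouse = 12,
                             seed = 11))
})

big_features <- function() fixture("big_features", function() {
  compute_cohort_features(big_sim()$cohort)
})

ALL_CLASSES <- c("F", "W", "D", "ASP", "ASN", "ASD", "ASI_F", "ASI_W",
                 "ASI_D")
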