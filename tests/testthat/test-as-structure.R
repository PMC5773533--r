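test_that("aligned profiles score half-open 5 s bins within the AS", {
  w <- standard_window()
  # single short AS [a, a+300] with one feeding event 30-40 s after onset
  a <- w[1] + 5000
  rec <- make_record(move_t = c(a, a + 300),
                     feed = rbind(c(a + 30, a + 40)), food_g = 0.1)
  part <- designate_states(rec, niche_home_base())
  prof <- as_aligned_profile(rec, part, "onset", "feed")
  expect_length(prof, 180)
  expect_equal(which(prof > 0), c(7L, 8L))   # bins [30,35) and [35,40)
  expect_true(all(prof %in% c(0, 1)))
  # no drinking events: all-zero profile
  expect_equal(as_aligned_profile(rec, part, "onset", "drink"), rep(0, 180))
  # bins beyond the AS extent (300 s = 60 bins) score 0
  expect_equal(sum(prof[61:180]), 0)
})

test_that("offset alignment places the final bin adjacent to the offset", {
  w <- standard_window()
  a <- w[1] + 5000
  rec <- make_record(move_t = c(a, a + 1200),
                     drink = rbind(c(a + 1195, a + 1199)), water_g = 0.1)
  part <- designate_states(rec, niche_home_base())
  prof <- as_aligned_profile(rec, part, "offset", "drink")
  expect_equal(which(prof > 0), 180L)
})

test_that("events of a neighboring AS are not attributed across states", {
  w <- standard_window()
  a <- w[1] + 5000
  # short AS (100 s), then a second AS 400 s later holding the feeding
  rec <- make_record(move_t = c(a, a + 100, a + 500, a + 600),
                     feed = rbind(c(a + 510, a + 520)), food_g = 0.1)
  part <- designate_states(rec, niche_home_base(), ist_s = 300)
  expect_equal(nrow(part$active), 2L)
  prof <- as_aligned_profile(rec, part, "onset", "feed")
  # the first AS's 15 min window spans the second AS's feeding event at
  # +510 s, but masking to the aligned AS keeps it out; only the second AS
  # scores, 10-20 s after its own onset (bins 3 and 4, each in 1 of 2 ASs)
  expect_equal(which(prof > 0), c(3L, 4L))
  expect_equal(prof[3], 0.5)
})

test_that("null model is seeded and uses the requested anchor count", {
  sim <- mini_sim()
  rec <- sim$cohort$records[[1]]
  part <- designate_states(rec, designate_home_base(rec))
  n1 <- null_model_profile(rec, part, "onset", "feed", k = 5, seed = 9)
  n2 <- null_model_profile(rec, part, "onset", "feed", k = 5, seed = 9)
  expect_identical(n1, n2)
  expect_length(n1, 180)
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_error(null_model_profile(rec, part, k = nrow(rec$movement) + 1),
               "fewer movement events")
})

test_that("Welch test matches an independent formula evaluation", {
  x <- c(27.5, 21.0, 19.0, 23.6, 17.0, 17.9, 16.9, 20.1, 21.9, 22.6, 23.1,
         19.6, 19.0, 21.7, 21.4)
  y <- c(27.1, 22.0, 20.8, 23.4, 23.4, 23.5, 25.8, 22.0, 24.8, 20.2, 21.9,
         22.1, 22.9, 30.5)
  res <- peak_significance(x, y)
  # direct Welch formulas
  se2 <- var(x) / length(x) + var(y) / length(y)
  t_ref <- (mean(x) - mean(y)) / sqrt(se2)
  df_ref <- se2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                     (var(y) / length(y))^2 / (length(y) - 1))
  expect_equal(res$t, t_ref, tolerance = 1e-6)
  expect_equal(res$df, df_ref, tolerance = 1e-6)
  expect_equal(res$p, 2 * pt(-abs(t_ref), df_ref), tolerance = 1e-6)
  # conventions at the degenerate ends
  expect_equal(peak_significance(c(1, 1), c(1, 1))$p, 1)
  sep <- peak_significance(c(1, 2, 3), c(11.0001, 12, 13.0002))
  expect_lt(sep$p, 0.001)
})

test_that("uniform feeding shows no onset structure against the null", {
  lib <- lapply(default_strain_library(2, seed = 13), function(sp) {
    sp$feed_onset_decay <- 0
    sp
  })
  cfg <- sim_config(lib, mice_per_strain = 2, days_per_mouse = 3, seed = 29)
  sim <- simulate_cohort(cfg)
  parts <- cohort_partitions(sim$cohort)
  pf <- mouse_profiles(sim$cohort, parts, "onset", "feed", seed = 4)
  # flat hazard: real and null peak levels agree within Monte Carlo error
  res <- peak_significance(apply(pf$real, 1, max), apply(pf$null, 1, max))
  expect_gt(res$p, 0.01)
})
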