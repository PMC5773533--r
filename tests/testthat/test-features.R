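test_that("event amounts are allocated proportionally to event time", {
  w <- standard_window()
  rec <- make_record(feed = rbind(w[1] + c(100, 130), w[1] + c(400, 470)),
                     food_g = 5)
  am <- assign_event_amounts(rec)
  expect_equal(am$amount_g, c(1.5, 3.5))   # 30 s and 70 s of 100 s -> 5 g
  single <- make_record(drink = rbind(w[1] + c(10, 20)), water_g = 0.7)
  expect_equal(assign_event_amounts(single)$amount_g, 0.7)
  none <- make_record()
  expect_equal(nrow(assign_event_amounts(none)), 0L)
})

test_that("bin features follow the interval-arithmetic definitions", {
  w <- standard_window()
  # AS = [ZT8, ZT9): half of bin 1, one AS of 60 min
  rec <- make_record(move_t = c(w[1], w[1] + 3600),
                     feed = rbind(w[1] + c(0, 2400)), food_g = 2)
  part <- designate_states(rec, niche_home_base(), ist_s = 1200)
  expect_equal(unname(part$active), cbind(w[1], w[1] + 3600))
  fe <- compute_day_features(rec, part)
  expect_equal(fe$ASP[1], 0.5)
  expect_equal(fe$ASP[-1], rep(0, 10))
  expect_equal(fe$ASN, c(1, rep(0, 10)))
  expect_equal(fe$ASD, c(60, rep(0, 10)))
  # 2 g over 40 min feeding, all inside 60 min of AS time in bin 1:
  # ASI_F = 2 g / 60 min
  expect_equal(fe$ASI_F[1], 2 / 60)
  expect_equal(fe$F[1], 2)
})

test_that("an ingestion event straddling a bin edge is prorated by overlap", {
  w <- standard_window()
  edge <- w[1] + 7200
  rec <- make_record(move_t = c(w[1], edge + 3600),
                     feed = rbind(c(edge - 30, edge + 90)), food_g = 1.2)
  part <- designate_states(rec, niche_home_base(), ist_s = 7200)
  fe <- compute_day_features(rec, part)
  expect_equal(fe$F[1:2], c(0.3, 0.9))
  expect_equal(sum(fe$F), rec$food_total_g)
})

test_that("distance is conserved under bin refinement and step assignment", {
  sim <- mini_sim()
  rec <- sim$cohort$records[[1]]
  part <- designate_states(rec, designate_home_base(rec))
  fe <- compute_day_features(rec, part)
  total <- sum(sqrt(diff(rec$movement$x)^2 + diff(rec$movement$y)^2))
  expect_equal(sum(fe$D), total, tolerance = 1e-9)
  # conservation of intake amounts across bins
  expect_equal(sum(fe$F), rec$food_total_g, tolerance = 1e-9)
  expect_equal(sum(fe$W), rec$water_total_g, tolerance = 1e-9)
  # ASP times bin length sums to total AS time
  expect_equal(sum(fe$ASP * 7200),
               sum(part$active[, 2] - part$active[, 1]), tolerance = 1e-9)
  # intensities finite wherever there is AS time
  expect_true(all(is.finite(fe$ASI_F[fe$ASP > 0])))
})

test_that("pattern correlations recover trivial and constructed relations", {
  # feature against itself and exact linear relations
  df <- data.frame(mouse_id = "m", strain = "s", day = 1,
                   feature = rep(c("A", "B", "C"), each = 11),
                   bin = rep(1:11, 3),
                   value = c(1:11, 2 * (1:11) + 3, rev(1:11)))
  out <- pattern_correlations(df, pairs = list(c("A", "A"), c("A", "B"),
                                               c("A", "C")))
  expect_equal(out$pearson_r, c(1, 1, -1), tolerance = 1e-12)
  expect_equal(out$spearman_rho, c(1, 1, -1), tolerance = 1e-12)
  # constant vector flagged, not NaN
  dfc <- data.frame(mouse_id = "m", strain = "s", day = 1,
                    feature = rep(c("A", "K"), each = 11),
                    bin = rep(1:11, 2), value = c(1:11, rep(2, 11)))
  outc <- pattern_correlations(dfc, pairs = list(c("A", "K")))
  expect_true(outc$constant)
  expect_true(is.na(outc$pearson_r))
})

test_that("ASP tracks intake patterns while a constant intensity does not", {
  # flat within-AS composition: intensity constant by construction
  lib <- lapply(default_strain_library(2, seed = 31), function(sp) {
    sp$feed_onset_decay <- 0
    sp$drink_offset_width_s <- 0
    sp
  })
  cfg <- sim_config(lib, mice_per_strain = 3, days_per_mouse = 4, seed = 63)
  fe <- compute_cohort_features(simulate_cohort(cfg)$cohort)
  out <- pattern_correlations(fe, pairs = list(c("ASP", "F"),
                                               c("ASI_F", "F")),
                              level = "strain")
  expect_gt(out$pearson_r[out$pair == "ASP~F"], 0.9)
  expect_lt(abs(out$pearson_r[out$pair == "ASI_F~F"]), 0.6)
})
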