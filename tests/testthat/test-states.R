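# Worked example: window-relative events, IST bridging and splitting.
worked_record <- function() {
  w <- standard_window()
  make_record(move_t = w[1] + c(100, 500, 2100),
              feed = rbind(w[1] + c(200, 260)),
              drink = rbind(w[1] + c(2000, 2060)),
              food_g = 0.1, water_g = 0.1)
}

test_that("gap bridging produces the expected Active States", {
  w <- standard_window()
  rec <- worked_record()
  part <- designate_states(rec, niche_home_base(), ist_s = 1200)
  expect_s3_class(part, "state_partition")
  expect_equal(unname(part$active),
               unname(cbind(w[1] + c(100, 2000), w[1] + c(500, 2100))))
  expect_equal(unname(part$inactive[, 1]), w[1] + c(0, 500, 2100))
  expect_equal(unname(part$inactive[, 2]), c(w[1] + c(100, 2000), w[2]))
  # the 1500 s gap is bridged once the threshold reaches it
  part2 <- designate_states(rec, niche_home_base(), ist_s = 1500)
  expect_equal(nrow(part2$active), 1L)
})

test_that("partition is exhaustive and disjoint; no events give one IS", {
  rec <- make_record()
  part <- designate_states(rec, niche_home_base())
  expect_equal(nrow(part$active), 0L)
  expect_equal(unname(part$inactive), matrix(standard_window(), nrow = 1))
  sim <- mini_sim()
  for (i in seq_along(sim$cohort$records)[1:6]) {
    rec <- sim$cohort$records[[i]]
    part <- designate_states(rec, niche_home_base())
    covered <- sum(part$active[, 2] - part$active[, 1]) +
      sum(part$inactive[, 2] - part$inactive[, 1])
    expect_equal(covered, diff(rec$window))
    both <- rbind(part$active, part$inactive)
    both <- both[order(both[, 1]), , drop = FALSE]
    expect_true(all(both[-1, 1] >= both[-nrow(both), 2] - 1e-9))
  }
})

test_that("movement events inside the home base do not seed activity", {
  w <- standard_window()
  # all movement inside niche cell 8; one feeding interval outside it
  rec <- mouse_day("t1", "TST", 1,
                   movement = data.frame(t = w[1] + c(100, 7000),
                                         x = c(19, 20), y = c(40, 41)),
                   ingestion = data.frame(kind = "feed", start = w[1] + 3000,
                                          end = w[1] + 3100),
                   food_total_g = 0.2)
  part <- designate_states(rec, niche_home_base())
  expect_equal(unname(part$active), cbind(w[1] + 3000, w[1] + 3100))
})

test_that("designation agrees exactly with the per-second oracle", {
  rec <- worked_record()
  hb <- niche_home_base()
  expect_equal(states_oracle(rec, hb, 1200)$active,
               designate_states(rec, hb, 1200)$active)
  sim <- mini_sim()
  for (i in seq_along(sim$cohort$records)) {
    rec <- sim$cohort$records[[i]]
    hb <- designate_home_base(rec)
    expect_identical(states_oracle(rec, hb)$active,
                     designate_states(rec, hb)$active)
  }
  expect_equal(nrow(states_oracle(make_record(), hb)$active), 0L)
})

test_that("idempotence: an AS's own events regenerate that AS", {
  sim <- mini_sim()
  rec <- sim$cohort$records[[1]]
  hb <- designate_home_base(rec)
  part <- designate_states(rec, hb)
  as1 <- part$active[1, ]
  sub <- mouse_day(rec$mouse_id, rec$strain, rec$day,
                   movement = rec$movement[rec$movement$t >= as1[1] &
                                             rec$movement$t <= as1[2], ],
                   ingestion = rec$ingestion[rec$ingestion$start >= as1[1] &
                                               rec$ingestion$end <= as1[2], ],
                   food_total_g = rec$food_total_g,
                   water_total_g = rec$water_total_g)
  part2 <- designate_states(sub, hb)
  expect_equal(unname(part2$active), unname(rbind(as1)))
})

test_that("AS counts are monotone non-increasing across the IST sweep", {
  rec <- worked_record()
  sw <- ist_sweep(rec, niche_home_base(), 60 * c(20, 25, 30))
  expect_equal(sw$n_as, c(2L, 1L, 1L))   # the 25 min gap bridges at 30 min
  sim <- mini_sim()
  for (i in seq_along(sim$cohort$records)[1:6]) {
    rec <- sim$cohort$records[[i]]
    sw <- ist_sweep(rec, designate_home_base(rec), 60 * seq(5, 60, 5))
    expect_true(all(diff(sw$n_as) <= 0))
  }
})

test_that("default simulated cohorts are robust over IST 15-30 min", {
  sim <- mini_sim()
  counts <- sapply(sim$cohort$records, function(rec)
    ist_sweep(rec, designate_home_base(rec), 60 * c(15, 20, 25, 30))$n_as)
  per_ist <- rowMeans(counts)
  expect_lt((max(per_ist) - min(per_ist)) / max(per_ist), 0.05)
})
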