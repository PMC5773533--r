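test_that("variance components match the hand-evaluated balanced formula", {
  m <- rbind(c(0, 2), c(10, 12))
  res <- broad_sense_heritability(m)
  expect_equal(res$MS_between, 100)
  expect_equal(res$MS_within, 2)
  expect_equal(res$V_g, 49)
  expect_equal(res$V_e, 2)
  expect_equal(res$H2, 49 / 51)
})

test_that("limit cases and clipping behave as defined", {
  # strain means differ, zero within-strain variance -> H2 = 1
  expect_equal(broad_sense_heritability(rbind(c(1, 1), c(5, 5)))$H2, 1)
  # equal strain means, positive within variance -> V_g clipped, H2 = 0
  expect_equal(broad_sense_heritability(rbind(c(0, 2), c(2, 0)))$H2, 0)
  # fully constant matrix: both components zero -> H2 = 0 by convention
  expect_equal(broad_sense_heritability(matrix(3, 2, 2))$H2, 0)
  expect_error(broad_sense_heritability(rbind(c(1, NA), c(2, 3))),
               "unbalanced")
})

test_that("estimates agree with a two-pass ANOVA oracle and are affine-invariant", {
  set.seed(4)
  for (rep in 1:5) {
    s <- sample(3:8, 1); n <- sample(3:8, 1)
    m <- matrix(rnorm(s * n, mean = rep(rnorm(s, sd = 2), n)), s, n)
    res <- broad_sense_heritability(m)
    # independent route: stats::lm / anova mean squares
    df <- data.frame(y = as.vector(m),
                     g = factor(rep(seq_len(s), n)))
    tab <- anova(stats::lm(y ~ g, df))
    vg <- max(0, (tab$`Mean Sq`[1] - tab$`Mean Sq`[2]) / n)
    expect_equal(res$V_g, vg, tolerance = 1e-10)
    expect_equal(res$V_e, tab$`Mean Sq`[2], tolerance = 1e-10)
    # affine invariance: shift and positive scale leave H2 unchanged
    res2 <- broad_sense_heritability(3.7 * m + 11)
    expect_equal(res2$H2, res$H2, tolerance = 1e-10)
  }
})

# Synthetic feature table: value = strain effect + mouse effect + day noise.
# The realized intraclass fraction (from the drawn effects, not their nominal
# variances) is returned alongside: with only s strain effects drawn, the
# realized genetic variance can sit well off its nominal value.
h2_table <- function(s, n, days, sg, se, sd_day, seed, feature = "ASP") {
  set.seed(seed)
  g <- rnorm(s, sd = sg)
  e_all <- numeric(0)
  rows <- list()
  for (i in seq_len(s)) for (j in seq_len(n)) {
    e <- rnorm(1, sd = se)
    e_all <- c(e_all, e)
    for (d in seq_len(days)) {
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = sprintf("s%02dm%02d", i, j),
        strain = sprintf("s%02d", i), day = d, feature = feature, bin = 1:11,
        value = g[i] + e + rnorm(11, sd = sd_day))
    }
  }
  vg <- mean((g - mean(g))^2)
  ve <- mean((e_all - mean(e_all))^2)
  list(table = do.call(rbind, rows), target = vg / (vg + ve))
}

test_that("bootstrap recovers the analytic intraclass fraction", {
  sim <- h2_table(s = 16, n = 9, days = 12, sg = 1, se = 1, sd_day = 0.1,
                  seed = 2024)
  res <- bootstrap_heritability(sim$table, "ASP", trials = 20,
                                n_per_strain = 9, seed = 5)
  expect_true(all(res$mean >= 0 & res$mean <= 1))
  # daily average of 11 bins and half of 12 days shrink the day noise to
  # near nothing; target = realized Vg / (Vg + Ve)
  expect_lt(abs(res$mean[["daily"]] - sim$target), 0.05)
  # determinism
  res2 <- bootstrap_heritability(sim$table, "ASP", trials = 20,
                                 n_per_strain = 9, seed = 5)
  expect_identical(res$mean, res2$mean)
  expect_identical(res$sd, res2$sd)
})

test_that("degenerate bootstrap inputs behave as specified", {
  fe <- h2_table(s = 3, n = 3, days = 4, sg = 1, se = 0, sd_day = 0,
                 seed = 9)$table
  res <- bootstrap_heritability(fe, "ASP", trials = 5, n_per_strain = 3,
                                seed = 1)
  expect_equal(unname(res$mean), rep(1, 12))
  expect_equal(unname(res$sd), rep(0, 12))
  expect_error(bootstrap_heritability(fe, "ASP", n_per_strain = 4),
               "fewer than")
  expect_error(bootstrap_heritability(fe, "XYZ"), "no rows")
})
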