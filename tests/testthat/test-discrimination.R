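# Literal transcription of the clustering-score definition, used as an
# independent oracle: counts computed group by group with table().
score_oracle <- function(truth, labels) {
  t_n <- length(truth)
  cnt <- function(v) if (length(v)) max(as.vector(table(factor(v, 1:2)))) else 0
  s_in <- (cnt(labels[truth == 1]) + cnt(labels[truth == 2])) / t_n
  s_out <- (cnt(truth[labels == 1]) + cnt(truth[labels == 2])) / t_n
  (s_in + s_out) / 2
}

test_that("clustering score matches its definition on worked cases", {
  expect_equal(clustering_score(c(1, 1, 2, 2), c(1, 1, 2, 2))$S, 1)
  ex <- clustering_score(c(1, 1, 2, 2), c(1, 2, 2, 2))
  expect_equal(ex$S_in, 0.75)
  expect_equal(ex$S_out, 0.75)
  expect_equal(ex$S, 0.75)
  # label swap: relabeling both groups simultaneously leaves S unchanged
  expect_equal(clustering_score(c(2, 2, 1, 1), c(2, 1, 1, 1))$S, 0.75)
  expect_error(clustering_score(c(1, 2), c(1, 2, 1)), "mismatch")
})

test_that("clustering score equals the enumeration oracle exhaustively", {
  t4 <- c(1, 1, 2, 2)
  for (code in 0:15) {
    L <- 1 + as.integer(intToBits(code)[1:4])
    expect_equal(clustering_score(t4, L)$S, score_oracle(t4, L))
  }
  set.seed(12)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    truth <- sample(1:2, n, replace = TRUE)
    L <- sample(1:2, n, replace = TRUE)
    expect_equal(clustering_score(truth, L)$S, score_oracle(truth, L))
  }
})

test_that("random labels score near one half at large t", {
  set.seed(31)
  truth <- rep(1:2, each = 5000)
  s <- replicate(50, clustering_score(truth,
                                      sample(1:2, 10000, TRUE))$S)
  expect_lt(abs(mean(s) - 0.5), 0.01)
})

test_that("pairwise K-means separates separable strains and not duplicates", {
  set.seed(7)
  # two point-mass-like strains at distinct locations
  x <- rbind(matrix(rnorm(40 * 11, 0, 0.01), 40),
             matrix(rnorm(40 * 11, 3, 0.01), 40))
  strain <- rep(c("A", "B"), each = 40)
  mouse <- rep(sprintf("m%d", 1:8), each = 10)
  res <- pairwise_cluster_accuracy(x, strain, mouse, trials = 5, seed = 2)
  expect_equal(unname(res$test[["mean"]]), 1)
  expect_equal(unname(res$train[["mean"]]), 1)
  # one distribution labeled as two strains: non-discriminative band
  x2 <- matrix(rnorm(80 * 11), 80)
  res2 <- pairwise_cluster_accuracy(x2, strain, mouse, trials = 10, seed = 3)
  expect_gt(res2$test[["mean"]], 0.4)
  expect_lt(res2$test[["mean"]], 0.8)
})

test_that("PCA projection has unit-variance columns and reconstructs M", {
  set.seed(21)
  m <- matrix(rnorm(60 * 11), 60) %*% diag(seq(3, 0.5, length.out = 11))
  model <- pca_projection(m)
  n_all <- model$scores
  expect_equal(colSums(n_all^2) / nrow(n_all), rep(1, ncol(n_all)),
               tolerance = 1e-8)
  expect_true(all(diff(model$d) <= 1e-9))
  # reconstruction M_centered = N D^{1/2} V^T
  mc <- sweep(m, 2, colMeans(m))
  rec <- n_all %*% diag(sqrt(model$d)) %*% t(model$V)
  expect_equal(rec, mc, tolerance = 1e-8)
  # diagonal case: first component along the largest-variance axis
  set.seed(22)
  d2 <- cbind(rnorm(2000, sd = 2), rnorm(2000, sd = 1), rnorm(2000, sd = 0.5),
              rnorm(2000, sd = 0.25))
  md <- pca_projection(d2)
  expect_gt(abs(md$V[1, 1]), 0.99)
  expect_equal(md$var_explained, sum(md$d[1:3]) / sum(md$d))
  # zero-variance feature dropped with a warning
  expect_warning(pca_projection(cbind(d2, 7)), "zero-variance")
})

test_that("strain ellipsoids summarize projected clouds", {
  set.seed(5)
  proj <- rbind(matrix(rnorm(30, -2, 0.3), 10),
                matrix(rnorm(30, 2, 0.3), 10))
  model <- list(projected = proj)
  ell <- strain_ellipsoids(structure(model, class = "pca_projection"),
                          rep(c("A", "B"), each = 10))
  expect_equal(unname(ell$A$center), colMeans(proj[1:10, ]))
  expect_equal(unname(ell$B$semi_axes), apply(proj[11:20, ], 2, sd))
  # symmetric strains have symmetric centers
  expect_equal(ell$A$center, -ell$B$center, tolerance = 0.5)
  expect_error(strain_ellipsoids(structure(model, class = "pca_projection"),
                                 c("A", rep("B", 19))), "fewer than 2")
  same <- rbind(proj[1:10, ], proj[1:10, ] * 0 + 1)
  expect_error(strain_ellipsoids(structure(list(projected = same),
                                           class = "pca_projection"),
                                 rep(c("A", "B"), each = 10)),
               "zero semi-axis")
})

test_that("Monte Carlo overlap matches closed forms", {
  sphere <- function(id, center)
    structure(list(id = id, center = center, semi_axes = c(1, 1, 1)),
              class = "strain_ellipsoid")
  # identical ellipsoids fully overlap; nested ellipsoid fully contained
  expect_equal(ellipsoid_overlap(sphere("a", c(0, 0, 0)),
                                 sphere("b", c(0, 0, 0)), seed = 4), 1)
  big <- structure(list(id = "big", center = c(0, 0, 0),
                        semi_axes = c(3, 3, 3)), class = "strain_ellipsoid")
  expect_equal(ellipsoid_overlap(big, sphere("w", c(0.5, 0, 0)), seed = 4), 1)
  # disjoint ellipsoids do not overlap
  expect_equal(ellipsoid_overlap(sphere("a", c(0, 0, 0)),
                                 sphere("b", c(5, 0, 0)), seed = 4), 0)
  # unit spheres 1 apart: lens volume fraction 5/16
  ov <- ellipsoid_overlap(sphere("a", c(0, 0, 0)), sphere("b", c(1, 0, 0)),
                          n_points = 10000, seed = 11)
  hits <- 10000 * pi / 6   # expected points inside W
  mc_sd <- sqrt(5 / 16 * (1 - 5 / 16) / hits)
  expect_lt(abs(ov - 5 / 16), 4 * mc_sd)
})

test_that("classifier separates simulated strains and respects exchangeability", {
  # two exchangeable strains: accuracy compatible with coin flipping
  lib <- default_strain_library(2, seed = 17)
  lib[[2]] <- lib[[1]]; lib[[2]]$strain_id <- "S02"
  cfg <- sim_config(lib, mice_per_strain = 4, days_per_mouse = 4, seed = 19)
  fe <- compute_cohort_features(simulate_cohort(cfg)$cohort)
  fm <- feature_matrix(fe, ALL_CLASSES)
  res <- strain_classifier(fm$x, fm$strain, fm$mouse, trials = 5, seed = 23)
  expect_gt(res$md[["mean"]], 0.3)
  expect_lt(res$md[["mean"]], 0.7)
})
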