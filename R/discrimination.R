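#' Two-group clustering accuracy score
#'
#' Given true group labels `T` and predicted labels `L` (both vectors of 1s
#' and 2s of length `t`): `I_g` is the count of the most common predicted
#' label within true group `g` and `S_in = (I_1 + I_2) / t`; `O_g` is the
#' count of the most common true label within predicted group `g` and
#' `S_out = (O_1 + O_2) / t`; the score is `S = (S_in + S_out) / 2`. An empty
#' predicted group contributes 0 to `S_out`. Perfect separation scores 1;
#' random labeling about 0.5.
#'
#' @param truth,labels integer vectors in `{1, 2}` of equal length.
#' @return list with `S`, `S_in`, `S_out`.
#' @export
clustering_score <- function(truth, labels) {
  if (length(truth) != length(labels)) stop("length mismatch")
  stopifnot(all(truth %in% 1:2), all(labels %in% 1:2))
  t_n <- length(truth)
  majority <- function(x) if (length(x)) max(tabulate(x, 2L)) else 0L
  s_in <- (majority(labels[truth == 1L]) + majority(labels[truth == 2L])) / t_n
  s_out <- (majority(truth[labels == 1L]) + majority(truth[labels == 2L])) / t_n
  list(S = (s_in + s_out) / 2, S_in = s_in, S_out = s_out)
}

# Stratified per-mouse split: for each mouse, floor(frac * k) of its items
# (at least 1) go to train.
stratified_split <- function(mouse, frac = 0.5) {
  train <- logical(length(mouse))
  for (m in unique(mouse)) {
    idx <- which(mouse == m)
    train[sample(idx, max(1L, floor(frac * length(idx))))] <- TRUE
  }
  train
}

scale_train <- function(x, train) {
  mu <- colMeans(x[train, , drop = FALSE])
  sg <- apply(x[train, , drop = FALSE], 2, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  list(x = sweep(sweep(x, 2, mu), 2, sg, "/"), mu = mu, sd = sg)
}

#' Pairwise strain discrimination by K-means clustering
#'
#' For two strains: per trial, half of each mouse's items form a train set;
#' K-means (K = 2, multiple restarts) on the standardized train vectors
#' yields two centroids; every train and test item is assigned to its nearest
#' centroid (Euclidean) and the [clustering_score()] computed against the
#' true strain labels.
#'
#' @param x numeric matrix of per-mouse-day feature vectors (e.g. the 11 ASP
#'   bins), rows = mouse-days.
#' @param strain character/factor vector of strain per row (exactly 2 levels).
#' @param mouse mouse id per row (each mouse needs >= 2 rows).
#' @param trials number of bootstrap trials.
#' @param seed seed.
#' @return list with `train` and `test`, each `c(mean, sd)` over trials, and
#'   `scores`, the trials x 2 matrix.
#' @export
pairwise_cluster_accuracy <- function(x, strain, mouse, trials = 20,
                                      seed = 1) {
  x <- as.matrix(x)
  strains <- sort(unique(as.character(strain)))
  if (length(strains) != 2L) stop("exactly two strains required")
  truth <- ifelse(as.character(strain) == strains[1L], 1L, 2L)
  if (min(table(mouse)) < 2L) stop("every mouse needs at least 2 mouse-days")
  sc <- with_seed(derive_seed(seed, "pairkm"), {
    t(vapply(seq_len(trials), function(tr) {
      train <- stratified_split(mouse, 0.5)
      st <- scale_train(x, train)
      km <- stats::kmeans(st$x[train, , drop = FALSE], centers = 2L,
                          nstart = 10L)
      d <- function(rows) {
        d1 <- rowSums(sweep(rows, 2, km$centers[1L, ])^2)
        d2 <- rowSums(sweep(rows, 2, km$centers[2L, ])^2)
        ifelse(d1 <= d2, 1L, 2L)
      }
      c(train = clustering_score(truth[train],
                                 d(st$x[train, , drop = FALSE]))$S,
        test = clustering_score(truth[!train],
                                d(st$x[!train, , drop = FALSE]))$S)
    }, c(train = 0, test = 0)))
  })
  list(train = c(mean = mean(sc[, 1L]), sd = stats::sd(sc[, 1L])),
       test = c(mean = mean(sc[, 2L]), sd = stats::sd(sc[, 2L])),
       scores = sc)
}

#' Cross-validated strain classification
#'
#' One-vs-rest L2-regularized logistic regression over all strains. Per
#' trial: a stratified per-mouse split at `train_fraction`; features
#' standardized on train statistics; one binomial ridge fit per strain;
#' held-out mouse-days classified by the largest one-vs-rest linear score
#' (mouse-day level), and each mouse classified from its averaged test-set
#' feature vector (mouse level).
#'
#' @param x numeric matrix of per-mouse-day feature vectors (11-D single
#'   class or 99-D concatenation of the nine classes).
#' @param strain strain label per row.
#' @param mouse mouse id per row.
#' @param train_fraction fraction of each mouse's mouse-days used for
#'   training.
#' @param trials number of trials.
#' @param seed seed.
#' @param C inverse regularization strength; the ridge penalty is
#'   `lambda = 1 / (C * n_train)`.
#' @return list with `md` and `mouse`, each `c(mean, sd)` of accuracy over
#'   trials, plus `per_trial` matrix.
#' @export
strain_classifier <- function(x, strain, mouse, train_fraction = 0.5,
                              trials = 20, seed = 1, C = 1) {
  x <- as.matrix(x)
  strain <- as.character(strain)
  classes <- sort(unique(strain))
  if (length(classes) < 2L) stop("need at least 2 strains")
  mouse_strain <- tapply(strain, mouse, `[`, 1L)
  acc <- with_seed(derive_seed(seed, "classifier"), {
    t(vapply(seq_len(trials), function(tr) {
      train <- stratified_split(mouse, train_fraction)
      if (length(unique(strain[train])) < 2L)
        stop("degenerate training fold: a single class")
      st <- scale_train(x, train)
      xtr <- st$x[train, , drop = FALSE]
      lambda <- 1 / (C * nrow(xtr))
      scores_for <- function(rows) {
        s <- vapply(classes, function(cl) {
          y <- as.integer(strain[train] == cl)
          # suppress glmnet's small-class advisory: one-vs-rest folds at
          # desk scale legitimately have few positives
          fit <- suppressWarnings(
            glmnet::glmnet(xtr, y, family = "binomial", alpha = 0,
                           lambda = lambda * c(100, 10, 1),
                           standardize = FALSE))
          as.numeric(stats::predict(fit, rows, s = lambda,
                                    type = "link"))
        }, numeric(nrow(rows)))
        classes[max.col(s, ties.method = "first")]
      }
      xte <- st$x[!train, , drop = FALSE]
      md_pred <- scores_for(xte)
      md_acc <- mean(md_pred == strain[!train])
      # mouse level: average each mouse's raw test vectors, then standardize
      te_mouse <- mouse[!train]
      avg <- t(vapply(unique(te_mouse), function(m)
        colMeans(x[!train, , drop = FALSE][te_mouse == m, , drop = FALSE]),
        numeric(ncol(x))))
      avg_std <- sweep(sweep(avg, 2, st$mu), 2, st$sd, "/")
      mouse_pred <- scores_for(avg_std)
      mouse_acc <- mean(mouse_pred == mouse_strain[unique(te_mouse)])
      c(md = md_acc, mouse = mouse_acc)
    }, c(md = 0, mouse = 0)))
  })
  list(md = c(mean = mean(acc[, 1L]), sd = stats::sd(acc[, 1L])),
       mouse = c(mean = mean(acc[, 2L]), sd = stats::sd(acc[, 2L])),
       per_trial = acc)
}

#' PCA projection of mouse-average feature vectors
#'
#' Columns are mean-centered; the covariance `C = (1/n) M^T M` is
#' eigendecomposed `C = V D V^T` with eigenvalues descending; the projected
#' coordinates are `N = M V D^{-1/2}`, so every projected column has unit
#' (population) variance. Zero-variance columns are dropped with a warning.
#'
#' @param m numeric matrix, rows = mice, columns = features (e.g. the 11 ASP
#'   bins of each mouse's mouse-day average).
#' @return object of class `pca_projection`: list with `center`, `V`, `d`
#'   (eigenvalues), `projected` (first 3 columns of N), `scores` (all
#'   columns), `var_explained` (top-3 eigenvalue fraction) and `kept`
#'   (columns used).
#' @export
pca_projection <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 4L) stop("need at least 4 mice")
  keep <- apply(m, 2L, stats::sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance feature(s) dropped")
    m <- m[, keep, drop = FALSE]
  }
  if (ncol(m) < 3L) stop("fewer than 3 varying features")
  center <- colMeans(m)
  mc <- sweep(m, 2L, center)
  cv <- crossprod(mc) / nrow(mc)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12
  v <- eg$vectors[, pos, drop = FALSE]
  d <- eg$values[pos]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(ncol(v))) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) v[, j] <- -v[, j]
  }
  n <- mc %*% v %*% diag(1 / sqrt(d), nrow = length(d))
  structure(list(center = center, V = v, d = d,
                 projected = n[, 1:3, drop = FALSE], scores = n,
                 var_explained = sum(d[1:3]) / sum(eg$values[eg$values > 0]),
                 kept = which(keep)),
            class = "pca_projection")
}

#' @export
print.pca_projection <- function(x, ...) {
  cat(sprintf("PCA projection: %d mice, %d components; top-3 variance explained %.1f%%\n",
              nrow(x$scores), length(x$d), 100 * x$var_explained))
  invisible(x)
}

#' Strain ellipsoids in projected space
#'
#' Per strain: center = mean of the mice's 3-D projected coordinates;
#' semi-axes = per-component standard deviation (axis-aligned, one sd).
#'
#' @param model a [pca_projection()].
#' @param strain strain label per row of the projection.
#' @return named list of objects of class `strain_ellipsoid` (fields `id`,
#'   `center`, `semi_axes`).
#' @export
strain_ellipsoids <- function(model, strain) {
  strain <- as.character(strain)
  stopifnot(length(strain) == nrow(model$projected))
  out <- lapply(sort(unique(strain)), function(s) {
    rows <- model$projected[strain == s, , drop = FALSE]
    if (nrow(rows) < 2L) stop("strain ", s, " has fewer than 2 mice")
    semi <- apply(rows, 2L, stats::sd)
    if (any(semi == 0)) stop("strain ", s, " has a zero semi-axis")
    structure(list(id = s, center = colMeans(rows), semi_axes = semi),
              class = "strain_ellipsoid")
  })
  names(out) <- sort(unique(strain))
  out
}

#' Monte Carlo overlap of two strain ellipsoids
#'
#' The larger-volume ellipsoid (product of semi-axes; ties broken by
#' lexicographic id) plays the container `V`; points are sampled uniformly in
#' the other ellipsoid `W`'s bounding box and the overlap is the fraction of
#' the points inside `W` that also fall inside `V`.
#'
#' @param e1,e2 `strain_ellipsoid` objects.
#' @param n_points Monte Carlo sample size.
#' @param seed seed.
#' @return overlap proportion in `[0, 1]`.
#' @export
ellipsoid_overlap <- function(e1, e2, n_points = 10000, seed = 1) {
  vol1 <- prod(e1$semi_axes); vol2 <- prod(e2$semi_axes)
  if (vol1 > vol2 || (vol1 == vol2 && e1$id <= e2$id)) {
    v <- e1; w <- e2
  } else {
    v <- e2; w <- e1
  }
  inside <- function(p, e)
    rowSums(sweep(sweep(p, 2L, e$center), 2L, e$semi_axes, "/")^2) <= 1
  with_seed(derive_seed(seed, "overlap"), {
    n <- n_points
    for (attempt in 1:5) {
      p <- sapply(1:3, function(j)
        stats::runif(n, w$center[j] - w$semi_axes[j],
                     w$center[j] + w$semi_axes[j]))
      in_w <- inside(p, w)
      if (any(in_w))
        return(sum(in_w & inside(p, v)) / sum(in_w))
      n <- n * 4L   # cannot occur for an axis-aligned box around W, in theory
    }
    stop("no sample landed in the reference ellipsoid")
  })
}
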