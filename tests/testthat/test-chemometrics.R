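test_that("PCA explained variance sums to 100 and matches the eigen oracle", {
  withr::with_seed(101, {
    X <- matrix(rnorm(20 * 5), 20, 5)
  })
  colnames(X) <- paste0("f", 1:5)
  p <- run_pca(X, ncomp = 5)
  expect_equal(sum(p$explained_pct_full), 100, tolerance = 1e-9)
  # oracle: eigenvalues of the correlation (autoscaled covariance) matrix
  ev <- eigen(stats::cor(X), symmetric = TRUE)$values
  expect_equal(p$explained_pct_full, 100 * ev / sum(ev), tolerance = 1e-9)
  # loadings orthonormal, scores centred
  expect_equal(crossprod(p$loadings), diag(5), tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(abs(colMeans(p$scores)) < 1e-10))
})

test_that("any full-rank 2-feature table explains 100 percent in 2 components", {
  withr::with_seed(5, {
    df <- tibble::tibble(
      fire = rnorm(30, 0.5, 0.05), ice = rnorm(30, 0.2, 0.02),
      label = rep(c("a", "b", "c"), 10)
    )
  })
  p <- run_pca(df, ncomp = 2)
  expect_equal(sum(p$explained_pct), 100, tolerance = 1e-9)
})

test_that("rank-1 data loads 100 percent on PC1", {
  x <- seq_len(12)
  X <- cbind(f1 = x, f2 = 3 * x - 2)
  p <- run_pca(X, ncomp = 2)
  expect_equal(p$explained_pct_full[1], 100, tolerance = 1e-9)
})

test_that("PCA reconstruction from all components reproduces the scaled data", {
  withr::with_seed(8, {
    X <- matrix(rnorm(15 * 4), 15, 4)
  })
  colnames(X) <- paste0("f", 1:4)
  p <- run_pca(X, ncomp = 4)
  Xs <- scale(X)
  attr(Xs, "scaled:center") <- attr(Xs, "scaled:scale") <- NULL
  expect_equal(p$scores %*% t(p$loadings), unclass(Xs),
    tolerance = 1e-9, ignore_attr = TRUE
  )
})

test_that("zero-variance columns are rejected by name under autoscaling", {
  X <- cbind(good = rnorm(10), dead = rep(2, 10))
  expect_error(run_pca(X), "dead")
})

test_that("PLS-DA separates well-separated Gaussian classes perfectly", {
  df <- make_gaussian_classes(n_per_class = 20, p = 2, dist = 6, sd = 1, seed = 1, k = 2)
  m <- plsda_fit(df, ncomp = 2)
  expect_equal(m$train_accuracy, 100)
  expect_true(all(abs(sqrt(colSums(m$weights^2)) - 1) < 1e-9))
  expect_lte(m$Q2, m$R2Y)
})

test_that("first PLS weight vector matches the dominant eigenvector of X'YY'X", {
  df <- make_gaussian_classes(n_per_class = 15, p = 4, dist = 5, seed = 2, k = 3)
  X <- scale(as.matrix(df[, paste0("f", 1:4)]))
  Y <- scale(fireice:::one_hot(factor(df$label)), scale = FALSE)
  m <- plsda_fit(df, ncomp = 2)
  M <- t(X) %*% Y %*% t(Y) %*% X
  v <- eigen(M, symmetric = TRUE)$vectors[, 1]
  cosine <- abs(sum(v * m$weights[, 1]))
  expect_equal(cosine, 1, tolerance = 1e-9)
})

test_that("randomly permuted labels destroy predictivity (Q2 near or below 0)", {
  df <- make_gaussian_classes(n_per_class = 15, p = 4, dist = 6, seed = 3, k = 3)
  perm <- withr::with_seed(2, sample(nrow(df)))
  m <- plsda_fit(df, labels = df$label[perm], ncomp = 2)
  expect_lt(m$Q2, 0.2)
  expect_lt(m$Q2, m$R2Y)
})

test_that("requesting more components than the rank truncates with a warning", {
  df <- make_gaussian_classes(n_per_class = 10, p = 2, dist = 5, seed = 4, k = 2)
  expect_warning(m <- plsda_fit(df, ncomp = 5), "truncat|exhaust")
  expect_lte(m$ncomp, 2)
})

test_that("VIP satisfies its algebraic identity and ranks informative features first", {
  df <- make_gaussian_classes(n_per_class = 15, p = 4, dist = 5, seed = 5, k = 3)
  m <- plsda_fit(df, ncomp = 3)
  expect_equal(sum(vip(m)^2), 4, tolerance = 1e-9)

  # p = 1 forces VIP = 1
  df1 <- tibble::tibble(
    f1 = c(rnorm(10), rnorm(10, 4)),
    label = rep(c("a", "b"), each = 10)
  )
  m1 <- plsda_fit(df1, ncomp = 1)
  expect_equal(unname(vip(m1)), 1, tolerance = 1e-9)

  # 4 informative + 4 pure-noise features: informative VIPs dominate
  base <- make_gaussian_classes(n_per_class = 20, p = 2, dist = 6, seed = 3, k = 3)
  withr::with_seed(3, {
    df2 <- dplyr::mutate(base,
      f3 = f1 + rnorm(60, 0, 0.5), f4 = f2 + rnorm(60, 0, 0.5),
      n1 = rnorm(60), n2 = rnorm(60), n3 = rnorm(60), n4 = rnorm(60)
    )
  })
  m2 <- plsda_fit(df2, ncomp = 3)
  v <- vip(m2)
  expect_gt(min(v[c("f1", "f2", "f3", "f4")]), max(v[c("n1", "n2", "n3", "n4")]))
  expect_equal(sum(v^2), 8, tolerance = 1e-9)
})

test_that("permutation test: shape, determinism, and minimal p on separable data", {
  df <- make_gaussian_classes(n_per_class = 10, p = 3, dist = 8, seed = 6, k = 3)
  pt <- permutation_test(df, ncomp = 2, nperm = 200, seed = 4)
  expect_equal(nrow(pt$results), 201)
  expect_equal(pt$p_value, 1 / 201, tolerance = 1e-12)
  expect_equal(pt$results$label_correlation[1], 1)
  # determinism under the same seed
  pt2 <- permutation_test(df, ncomp = 2, nperm = 200, seed = 4)
  expect_equal(pt$results, pt2$results, tolerance = 1e-12)
})

test_that("feature rows identical up to noise carry no class information", {
  withr::with_seed(99, {
    df <- tibble::tibble(
      f1 = 1.5 + rnorm(24, 0, 1e-6), # constant rows up to numerical jitter
      f2 = 2.5 + rnorm(24, 0, 1e-6),
      label = rep(c("a", "b", "c"), each = 8)
    )
  })
  pt <- suppressWarnings(permutation_test(df, ncomp = 1, nperm = 39, seed = 9))
  expect_gt(pt$p_value, 0.05)
})

test_that("anova_pvalues matches hand-computed mean squares and handles edge cases", {
  # 3 groups x 3 values, worked by hand: group means 2/5/8, grand mean 5,
  # SSB = 3*(9+0+9) = 54, SSW = 2+2+2 = 6
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("g1", "g2", "g3"), each = 3)
  df <- tibble::tibble(f = x, label = g)
  res <- anova_pvalues(df)
  f_hand <- (54 / 2) / (6 / 6) # MSB / MSW = 27
  expect_equal(res$f_statistic, f_hand, tolerance = 1e-9)
  expect_equal(res$p_value, stats::pf(f_hand, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  # identical groups: F = 0, p = 1
  df0 <- tibble::tibble(f = rep(c(1, 2, 3), 2), label = rep(c("a", "b"), each = 3))
  r0 <- anova_pvalues(df0)
  expect_equal(r0$f_statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)

  # complete separation with tiny jitter
  dfs <- tibble::tibble(
    f = c(0, 0, 0, 5, 5, 5) + c(0, 1e-9, -1e-9, 0, 1e-9, -1e-9),
    label = rep(c("a", "b"), each = 3)
  )
  expect_lt(anova_pvalues(dfs)$p_value, 1e-6)

  # all-constant feature: degenerate rule p := 1
  dfc <- tibble::tibble(f = rep(7, 6), label = rep(c("a", "b"), each = 3))
  expect_equal(anova_pvalues(dfc)$p_value, 1)
})

test_that("select_markers applies the strict VIP > 1 and p < 0.05 rule", {
  out <- select_markers(c(a = 1.2, b = 0.9), c(0.01, 0.01))
  expect_identical(out$feature, "a")
  expect_equal(nrow(select_markers(c(a = 1.2), c(0.10))), 0)
  # boundary values are excluded (strict inequalities)
  expect_equal(nrow(select_markers(c(a = 1.0, b = 2), c(0.01, 0.05))), 0)
  expect_error(select_markers(c(1, 2), c(0.1)), "equal length")
})

test_that("PLS-DA agrees with an independent implementation on component 1", {
  skip_if_not_installed("mixOmics")
  df <- make_gaussian_classes(n_per_class = 12, p = 4, dist = 4, seed = 10, k = 3)
  X <- as.matrix(df[, paste0("f", 1:4)])
  m <- plsda_fit(df, ncomp = 2, cv_folds = 0)
  ref <- mixOmics::plsda(X, factor(df$label), ncomp = 2, scale = TRUE)
  cosine <- abs(stats::cor(m$scores[, 1], ref$variates$X[, 1]))
  expect_gt(cosine, 0.999)
})
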