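test_that("PCA reduces 48 features to 9 centered, sign-fixed scores", {
  coh <- simulate_cohort_series(phantom_config(), build_default_schedule(),
                                18, 17, seed = 3)
  fm <- cohort_feature_matrix(coh)[["forehead.LVHA"]]
  out <- pca_reduce(fm, 9)
  expect_equal(dim(out$reduced$values), c(35, 9))
  expect_equal(colMeans(out$reduced$values), rep(0, 9), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(crossprod(out$model$loadings), diag(9), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(out$model$explained_variance) <= 1e-12))
  for (j in 1:9) {
    l <- out$model$loadings[, j]
    expect_gte(l[which.max(abs(l))], 0)
  }
  expect_identical(out$reduced$labels, fm$labels)
  expect_error(pca_reduce(fm, 35), "exceeds")
})

test_that("full-rank PCA reconstructs the input and degenerate input gives zeros", {
  withr::with_seed(5, X <- matrix(rnorm(10 * 6), 10, 6))
  fm <- thermoface:::new_feature_matrix(
    X, factor(rep(c("moderate", "marked"), each = 5),
              levels = c("moderate", "marked")), "nose", "HVLA")
  out <- pca_reduce(fm, 6)
  recon <- out$reduced$values %*% t(out$model$loadings)
  recon <- sweep(recon, 2, out$model$means, "+")
  expect_equal(recon, X, tolerance = 1e-8, ignore_attr = TRUE)
  fm0 <- fm; fm0$values <- matrix(3, 10, 6)
  out0 <- pca_reduce(fm0, 2)
  expect_equal(out0$reduced$values, matrix(0, 10, 2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(out0$model$explained_variance, c(0, 0))
})

test_that("PCA scores are invariant under row reordering", {
  fm <- random_block(10, 10, p = 12, seed = 8)
  out <- pca_reduce(fm, 4)
  perm <- sample(20)
  fm2 <- fm; fm2$values <- fm$values[perm, ]; fm2$labels <- fm$labels[perm]
  out2 <- pca_reduce(fm2, 4)
  expect_equal(out2$reduced$values, out$reduced$values[perm, ],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("Wilks F equals the Hotelling T-squared oracle on random instances", {
  worst <- 0
  for (i in 1:100) {
    fm <- random_block(18, 17, p = 9, seed = i)
    res <- manova_wilks(fm)
    ora <- hotelling_f(fm$values, fm$labels)
    worst <- max(worst, abs(res$f_value - ora$f))
    expect_equal(res$df1, ora$df1)
    expect_equal(res$df2, ora$df2)
  }
  expect_lt(worst, 1e-10)
})

test_that("degrees of freedom are (9, 25) for 35 subjects and 9 components", {
  res <- manova_wilks(random_block(18, 17, p = 9, seed = 1))
  expect_identical(c(res$df1, res$df2), c(9L, 25L))
})

test_that("k = 1 MANOVA equals the squared pooled-variance t test", {
  for (i in 1:10) {
    fm <- random_block(12, 9, p = 1, seed = 100 + i, shift = 0.4)
    res <- manova_wilks(fm)
    tt <- stats::t.test(fm$values[, 1] ~ fm$labels, var.equal = TRUE)
    expect_equal(res$f_value, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_identical(c(res$df1, res$df2), c(1L, 19L))
    expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)
  }
})

test_that("Wilks F matches the stats::manova reference implementation", {
  fm <- random_block(18, 17, p = 5, seed = 77, shift = 0.3)
  res <- manova_wilks(fm)
  ref <- summary(stats::manova(fm$values ~ fm$labels), test = "Wilks")
  stats_row <- ref$stats[1, ]
  expect_equal(res$wilks_lambda, unname(stats_row["Wilks"]),
               tolerance = 1e-8)
  expect_equal(res$f_value, unname(stats_row["approx F"]), tolerance = 1e-8)
})

test_that("no between-group variation gives Lambda 1, F 0, p 1", {
  withr::with_seed(3, X <- matrix(rnorm(6 * 3), 6, 3))
  fm <- thermoface:::new_feature_matrix(
    rbind(X, X), factor(rep(c("moderate", "marked"), each = 6),
                        levels = c("moderate", "marked")), "mouth", "LVLA")
  res <- manova_wilks(fm)
  expect_equal(res$wilks_lambda, 1, tolerance = 1e-12)
  expect_equal(res$f_value, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
})

test_that("Lambda stays in (0, 1] and p falls as the planted gap grows", {
  lambdas <- c(); ps <- c()
  for (gap in c(0, 0.3, 0.6, 1, 1.6)) {
    fm <- random_block(18, 17, p = 9, seed = 42, shift = gap)
    res <- manova_wilks(fm)
    lambdas <- c(lambdas, res$wilks_lambda)
    ps <- c(ps, res$p_value)
  }
  expect_true(all(lambdas > 0 & lambdas <= 1))
  expect_true(all(diff(ps) < 0))
})

test_that("singular within-group covariance is reported, not silently inverted", {
  withr::with_seed(2, X <- matrix(rnorm(10 * 2), 10, 2))
  X <- cbind(X, X[, 1] + X[, 2])        # exactly collinear third column
  fm <- thermoface:::new_feature_matrix(
    X, factor(rep(c("moderate", "marked"), each = 5),
              levels = c("moderate", "marked")), "nose", "REST")
  expect_error(manova_wilks(fm), "singular")
  small <- random_block(2, 2, p = 9, seed = 3)
  expect_error(manova_wilks(small), "too few subjects")
  one <- random_block(1, 5, p = 2, seed = 3)
  expect_error(manova_wilks(one), "at least 2")
})

test_that("the results table covers all 20 cells with stars and flags missing blocks", {
  coh <- simulate_cohort_series(phantom_config(), build_default_schedule(),
                                18, 17, seed = 6)
  blocks <- cohort_feature_matrix(coh)
  tab <- table2_analysis(blocks, k = 9)
  expect_equal(nrow(tab), 20)
  expect_setequal(unique(tab$roi), c("forehead", "nose", "mouth",
                                     "left_cheek", "right_cheek"))
  expect_setequal(unique(tab$emotion), emotion_levels())
  expect_true(all(tab$stars[tab$p_value < 0.001] == "***"))
  expect_true(all(tab$stars[tab$p_value >= 0.05] == ""))
  expect_error(table2_analysis(blocks[-1], k = 9), "missing feature block")
  # identical blocks give identical statistics
  same <- blocks
  for (key in names(same)) same[[key]] <- blocks[[1]]
  tab_same <- table2_analysis(same, k = 9)
  expect_equal(length(unique(tab_same$f_value)), 1)
  # bonferroni never decreases p
  tab_b <- table2_analysis(blocks, k = 9, adjust = "bonferroni")
  expect_true(all(tab_b$p_value >= tab$p_value - 1e-15))
})

test_that("per-cell failures become NA cells when tolerated", {
  coh <- simulate_cohort_series(phantom_config(), short_schedule(),
                                1, 1, seed = 1)
  blocks <- cohort_feature_matrix(coh, short_schedule())
  expect_error(table2_analysis(blocks, k = 9), "cell")
  tab <- table2_analysis(blocks, k = 9, on_error = "na")
  expect_true(all(is.na(tab$p_value)))
  expect_true(all(nzchar(tab$note)))
})
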