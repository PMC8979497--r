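test_that("standardization produces exact z-scores and stores the scaler", {
  tab <- data.frame(subject_id = c("a", "b", "c"), x = c(1, 2, 3),
                    y = c(10, 30, 20))
  z <- standardize(tab)
  expect_equal(unname(z$values[, "x"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(z$values)), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(apply(z$values, 2, sd)), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(z$means), c(2, 20))
  tab$cst <- 5
  expect_error(standardize(tab), "zero-variance")
  expect_error(standardize(tab[1, ]), "at least 2")
  tab2 <- data.frame(subject_id = 1:3, x = c(1, NA, 3))
  expect_error(standardize(tab2, "x"), "undefined")
})

test_that("Hopkins statistic: ~0.5 on uniform data, high on tight blobs", {
  un <- uniform_null(500, 2, seed = 21)
  expect_equal(hopkins_statistic(un, n_draws = 100, seed = 22), 0.5,
               tolerance = 0.1)  # |H - 0.5| < 0.05
  blobs <- with_seed(20, rbind(matrix(rnorm(400, 0, 0.05), 200, 2),
                               matrix(rnorm(400, 10, 0.05), 200, 2)))
  expect_gt(hopkins_statistic(blobs, seed = 23), 0.8)
  expect_error(hopkins_statistic(matrix(rnorm(10), 5, 2)), "at least 10")
})

test_that("PCA on the correlation matrix with deterministic sign convention", {
  # two perfectly correlated variables: PC1 carries 100%
  tab <- data.frame(subject_id = 1:10, a = 1:10, b = 2 * (1:10) + 3)
  p <- ul_pca(standardize(tab))
  expect_equal(p$pct_variance[1], 100, tolerance = 1e-9)

  # exactly orthogonal, equal-variance columns: exactly 20% each
  q <- poly(1:40, 5)
  colnames(q) <- paste0("v", 1:5)
  p2 <- ul_pca(standardize(as.data.frame(q)))
  expect_equal(p2$pct_variance, rep(20, 5), tolerance = 1e-9)

  set.seed(5)
  tab3 <- as.data.frame(matrix(rnorm(200), 40, 5))
  z3 <- standardize(tab3)
  p3 <- ul_pca(z3)
  expect_equal(sum(p3$pct_variance), 100, tolerance = 1e-6)
  expect_true(all(diff(p3$eigenvalues) <= 1e-12))
  # loadings orthonormal, largest-magnitude loading positive per component
  expect_equal(crossprod(p3$loadings), diag(5), tolerance = 1e-9,
               ignore_attr = TRUE)
  for (j in 1:5)
    expect_gt(p3$loadings[which.max(abs(p3$loadings[, j])), j], 0)
  # reconstruction from scores and loadings reproduces z
  expect_equal(p3$scores %*% t(p3$loadings), z3$values, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("k-means: boundary cases, exact recovery, variance identities", {
  set.seed(6)
  x <- matrix(rnorm(60), 30, 2)
  s1 <- kmeans_fit(x, 1, seed = 1)
  expect_equal(as.numeric(s1$centroids), colMeans(x))
  expect_equal(s1$pct_total_variance, 0, tolerance = 1e-9)
  sn <- kmeans_fit(x, 30, seed = 2)
  expect_equal(sn$wss, 0, tolerance = 1e-9)
  expect_equal(sn$pct_total_variance, 100, tolerance = 1e-9)

  # planted spherical clusters separated by 10 sigma: perfect recovery
  truth <- rep(1:3, each = 100)
  xx <- matrix(rnorm(600), 300, 2) + 10 * cbind(truth %% 2, truth %/% 2)
  sol <- kmeans_fit(xx, 3, seed = 3)
  expect_equal(ari(sol$assignments, truth), 1.0)
  expect_equal(sol$bss + sol$wss, sol$tss, tolerance = 1e-6 * sol$tss)
  expect_true(all(tabulate(sol$assignments, 3) > 0))

  # full determinism given seed
  sol2 <- kmeans_fit(xx, 3, seed = 3)
  expect_identical(sol$assignments, sol2$assignments)
  expect_identical(sol$wss, sol2$wss)
})

test_that("elbow/silhouette/gap diagnostics select the planted k", {
  set.seed(31)
  blobs <- rbind(matrix(rnorm(160), 80, 2), matrix(rnorm(160, 8), 80, 2))
  d <- choose_k_diagnostics(blobs, k_range = 1:6, seed = 32)
  expect_true(all(diff(d$wss) <= 1e-8))  # elbow curve non-increasing
  expect_equal(attr(d, "k_silhouette"), 2)
  expect_equal(attr(d, "k_gap"), 2)
  un <- uniform_null(120, 2, seed = 33)
  d1 <- choose_k_diagnostics(un, k_range = 1:6, seed = 34)
  expect_equal(attr(d1, "k_gap"), 1)
})

test_that("MANOVA refit matches the hand-computed Gaussian likelihood", {
  # n = 4, q = 1, k = 2, values {0,0,10,10}: within-cluster variance is 0,
  # guarded by the documented 1e-6 ridge
  x <- matrix(c(0, 0, 10, 10), 4, 1)
  out <- manova_refit_aic(x, c(1, 1, 2, 2))
  ll <- -2 * (log(2 * pi) + log(1e-6))
  expect_equal(out$loglik, ll, tolerance = 1e-9)
  expect_equal(out$n_params, 3)
  expect_equal(out$aic, -2 * ll + 6, tolerance = 1e-9)

  set.seed(35)
  truth <- rep(1:3, each = 60)
  xx <- matrix(rnorm(360), 180, 2) + 4 * cbind(truth == 2, truth == 3)
  expect_lt(manova_refit_aic(xx, truth)$aic,
            manova_refit_aic(xx, rep(1, 180))$aic)
  expect_lt(manova_refit_aic(xx, truth)$aic,
            manova_refit_aic(xx, sample(truth))$aic)
  expect_error(manova_refit_aic(xx, truth[-1]), "length")
})

test_that("the model ladder fixes its variable subsets and k-orderings", {
  expect_equal(ul_variable_names(5),
               c("hours_p", "hours_np", "med_accel_p", "accel_var_p",
                 "use_ratio"))
  expect_equal(setdiff(ul_variable_names(12), ul_variable_names(9)),
               c("jerk_asym", "sparc_p", "sparc_np"))
  expect_equal(setdiff(ul_variable_names(9), ul_variable_names(7)),
               c("iso_hours_p", "iso_hours_np"))
  expect_equal(setdiff(ul_variable_names(7), ul_variable_names(5)),
               c("bilateral_magnitude", "magnitude_ratio"))

  # small synthetic cohort: total variance non-decreasing in k per subset
  arch <- ul_archetypes(n_subjects = c(8, 8, 8, 8, 8))
  sim <- generate_cohort(arch, seed = 36, raw = TRUE)
  tab <- compute_metric_table(sim$series, sim$raw)
  lad <- run_model_ladder(tab, seed = 37)
  expect_equal(nrow(lad), 12)
  for (nv in c(12, 9, 7, 5)) {
    ptv <- lad$pct_total_variance[lad$n_vars == nv][order(lad$k[lad$n_vars == nv])]
    expect_true(all(diff(ptv) >= -1e-8))
  }
  sols <- attr(lad, "solutions")
  s <- sols[["5_5"]]
  expect_equal(s$bss + s$wss, s$tss, tolerance = 1e-6 * s$tss)
})
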