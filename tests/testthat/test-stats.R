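test_that("shape PCA reconstructs the data and matches an SVD eigenvalue oracle", {
  X <- equimorph:::with_seed(71, matrix(rnorm(30 * 12), 30, 12))
  pca <- shape_pca(X, threshold = 0.99)
  recon <- sweep(pca$scores %*% t(pca$vectors), 2, pca$mean, `+`)
  expect_lt(max(abs(recon - X)), 1e-8)
  expect_lt(max(abs(colMeans(pca$scores))), 1e-10)
  expect_equal(sum(pca$eigenvalues), pca$total_variance, tolerance = 1e-8)

  ## independent oracle: eigenvalues of the covariance matrix
  want <- eigen(cov(X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pca$eigenvalues, want[seq_along(pca$eigenvalues)], tolerance = 1e-8)

  ## data on an exact 2D plane: exactly 2 nonzero eigenvalues
  basis <- matrix(rnorm(12 * 2), 12, 2)
  Xp <- equimorph:::with_seed(72, matrix(rnorm(20 * 2), 20, 2)) %*% t(basis)
  pp <- shape_pca(Xp)
  expect_identical(length(pp$eigenvalues), 2L)

  ## retention rule: smallest m with cumulative variance >= threshold
  cum <- cumsum(pca$eigenvalues) / pca$total_variance
  expect_true(cum[pca$retained] >= 0.99)
  expect_true(pca$retained == 1 || cum[pca$retained - 1] < 0.99)
})

test_that("permutation shape ANOVA: zero SS for identical shapes, sequential SS adds up", {
  Y0 <- matrix(rep(c(1, 2, 3, 4), each = 18), 18, 4)
  g <- factor(rep(letters[1:3], each = 6))
  h <- factor(rep(1:2, 9))
  fit0 <- shape_anova(Y0 ~ g * h, data = list(Y0 = Y0, g = g, h = h),
                      n_perm = 99, seed = 1)
  expect_lt(max(fit0$table$SS[1:3]), 1e-20)

  Y <- equimorph:::with_seed(73, matrix(rnorm(18 * 6), 18, 6))
  fit <- shape_anova(Y ~ g * h, data = list(Y = Y, g = g, h = h),
                     n_perm = 199, seed = 2)
  tab <- fit$table
  expect_equal(sum(tab$SS[1:4]), tab$SS[5], tolerance = 1e-8)   # terms+resid = total
  expect_equal(tab$Rsq[1:3], tab$SS[1:3] / tab$SS[5], tolerance = 1e-12)
  ## Rsq decomposition holds in the other factor order too
  fit_rev <- shape_anova(Y ~ h * g, data = list(Y = Y, g = g, h = h),
                         n_perm = 99, seed = 2)
  expect_equal(sum(fit_rev$table$SS[1:4]), fit_rev$table$SS[5], tolerance = 1e-8)
})

test_that("single-factor F equals Goodall's F from a direct Procrustes-distance oracle", {
  sch <- tiny_scheme()
  st <- fixture_study(seed = 74, scheme = sch)
  al <- align_study(st, scheme = sch, slide = FALSE)
  Y <- al$joint$shapes
  g <- factor(al$meta$taxon)
  fit <- shape_anova(Y ~ g, data = list(Y = Y, g = g), n_perm = 99, seed = 3)

  ## Goodall's F: between/within sums of squared deviations of (Procrustes)
  ## coordinates around group means, via squared Euclidean distances
  n <- nrow(Y); k <- nlevels(g)
  gm <- colMeans(Y)
  means <- rowsum(Y, g) / as.vector(table(g))
  ssb <- sum(as.vector(table(g)) * rowSums(sweep(means, 2, gm)^2))
  ssw <- sum((Y - means[g, ])^2)
  f_goodall <- (ssb / (k - 1)) / (ssw / (n - k))
  expect_equal(fit$table$F[1], f_goodall, tolerance = 1e-10)
})

test_that("shape ANOVA agrees with an independent distance-based implementation", {
  skip_if_not_installed("vegan")
  Y <- equimorph:::with_seed(75, matrix(rnorm(24 * 5), 24, 5))
  g <- factor(rep(letters[1:3], each = 8))
  h <- factor(rep(1:2, 12))
  fit <- shape_anova(Y ~ g * h, data = list(Y = Y, g = g, h = h),
                     n_perm = 99, seed = 4)
  ad <- vegan::adonis2(dist(Y) ~ g * h, data = data.frame(g = g, h = h),
                       permutations = 99, by = "terms")
  expect_equal(fit$table$SS[1:3], ad$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(fit$table$F[1:3], ad$F[1:3], tolerance = 1e-8)
  expect_equal(fit$table$Rsq[1:3], ad$R2[1:3], tolerance = 1e-8)
})

test_that("MANOVA Pillai: null case near zero, two-group case matches Hotelling oracle", {
  set.seed(76)
  X <- matrix(rnorm(60 * 3), 60, 3)
  g_null <- factor(rep(1:3, each = 20))
  m0 <- manova_pillai(X, g_null)
  expect_lt(m0$pillai, 0.3)
  expect_gt(m0$p, 0.01)

  ## two groups: Pillai = T2/(T2 + den df)
  g2 <- factor(rep(1:2, each = 30))
  X2 <- X; X2[31:60, 1] <- X2[31:60, 1] + 1.5
  m2 <- manova_pillai(X2, g2)
  n1 <- 30; n2 <- 30
  d <- colMeans(X2[1:30, ]) - colMeans(X2[31:60, ])
  Sp <- (cov(X2[1:30, ]) * (n1 - 1) + cov(X2[31:60, ]) * (n2 - 1)) / (n1 + n2 - 2)
  T2 <- (n1 * n2) / (n1 + n2) * as.numeric(t(d) %*% solve(Sp) %*% d)
  expect_equal(m2$pillai, T2 / (T2 + (n1 + n2 - 2)), tolerance = 1e-10)

  expect_error(manova_pillai(matrix(rnorm(10 * 10), 10, 10), factor(rep(1:2, 5))),
               "fewer PCs")
})
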