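make_groups <- function(n_per = 10, sep = 5, m = 4, g = 3, seed = 81) {
  equimorph:::with_seed(seed, {
    centers <- matrix(rnorm(g * m), g, m) * sep
    X <- do.call(rbind, lapply(1:g, function(i)
      sweep(matrix(rnorm(n_per * m), n_per, m), 2, centers[i, ], `+`)))
    list(X = X, g = factor(rep(letters[1:g], each = n_per)))
  })
}

test_that("CVA: axis count, unit pooled within-group variance, brute-force angle oracle", {
  d <- make_groups()
  fit <- cva(d$X, d$g)
  expect_identical(ncol(fit$axes), 2L)            # min(g-1, m)

  ## canonical variates have unit pooled within-group variance
  for (j in seq_len(ncol(fit$scores))) {
    v <- fit$scores[, j]
    w <- tapply(v, d$g, function(z) sum((z - mean(z))^2))
    expect_equal(sum(w) / (length(v) - nlevels(d$g)), 1, tolerance = 1e-8)
  }

  ## 2-group 2-variable toy: leading axis maximizes between/within ratio
  equimorph:::with_seed(82, {
    X2 <- rbind(matrix(rnorm(40), 20, 2),
                sweep(matrix(rnorm(40), 20, 2), 2, c(3, 1), `+`))
  })
  g2 <- factor(rep(1:2, each = 20))
  fit2 <- cva(X2, g2)
  expect_identical(ncol(fit2$axes), 1L)
  ratio <- function(theta) {
    a <- c(cos(theta), sin(theta))
    v <- X2 %*% a
    sb <- sum(tapply(v, g2, function(z) length(z) * (mean(z) - mean(v))^2))
    sw <- sum(tapply(v, g2, function(z) sum((z - mean(z))^2)))
    sb / sw
  }
  best <- max(vapply(seq(0, pi, by = 1e-3), ratio, 0))
  got <- ratio(atan2(fit2$axes[2, 1], fit2$axes[1, 1]))
  expect_equal(got, best, tolerance = 1e-4)

  expect_error(cva(d$X[c(1:10, 11), ], droplevels(d$g[c(1:10, 11)])), "single specimen")
})

test_that("cross-validated classification: perfect separation gives CCV 100", {
  d <- make_groups(n_per = 8, sep = 20)
  rep <- crossval_classify(d$X, d$g, rounds = 100, seed = 5)
  expect_equal(rep$ccv, 100)
  expect_equal(rep$ccv_modal, 100)
  expect_equal(unname(diag(as.matrix(rep$confusion))), rep(1, 3), tolerance = 1e-12)
  ## per-specimen assignment rates sum to 1
  rates <- as.matrix(rep$per_specimen[, levels(d$g)])
  expect_equal(rowSums(rates), rep(1, nrow(rates)), tolerance = 1e-9)
})

test_that("classification is invariant to invertible affine transforms of the scores", {
  d <- make_groups(n_per = 6, sep = 2, m = 3, seed = 83)
  A <- matrix(c(2, 0.5, -1, 0.3, 1.5, 0.2, 0, -0.7, 1.1), 3, 3)
  b <- c(4, -2, 7)
  Xt <- sweep(d$X %*% A, 2, b, `+`)
  r1 <- crossval_classify(d$X, d$g, rounds = 50, seed = 9)
  r2 <- crossval_classify(Xt, d$g, rounds = 50, seed = 9)
  expect_equal(r1$ccv, r2$ccv, tolerance = 1e-6)
  expect_equal(as.matrix(r1$confusion), as.matrix(r2$confusion), tolerance = 1e-6)
})

test_that("groups of size 2 split 1 training / 1 testing and still classify", {
  d <- make_groups(n_per = 6, sep = 15, m = 2, g = 3, seed = 84)
  X <- rbind(d$X, matrix(c(30, 30, 30.5, 29.5), 2, 2, byrow = TRUE))
  g <- factor(c(as.character(d$g), "tiny", "tiny"))
  rep <- crossval_classify(X, g, rounds = 60, seed = 11)
  expect_gt(rep$ccv, 95)
  expect_equal(unname(rep$ccv_per_group[4]), 100, tolerance = 1e-9)
})

test_that("a score row equidistant from two centroids gets a uniform posterior", {
  d <- make_groups(n_per = 12, sep = 3, m = 2, g = 2, seed = 85)
  fit <- cva(d$X, d$g)
  mid <- (colMeans(d$X[d$g == "a", ]) + colMeans(d$X[d$g == "b", ])) / 2
  pr <- predict(fit, matrix(mid, 1))
  expect_equal(unname(pr$posterior[1, ]), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("predict_unknown superimposes a raw configuration into the trained space", {
  sch <- tiny_scheme()
  st <- fixture_study(seed = 88, scheme = sch)
  al <- align_study(st, scheme = sch, slide = FALSE)
  pca <- shape_pca(al$joint$shapes)
  g <- factor(al$meta$taxon)
  fit <- cva(retained_scores(pca), g)

  ## take a training specimen's raw configuration, re-transform it arbitrarily:
  ## it must come back to its own taxon
  sp <- st$specimens[[5]]
  if (sp$side == "right") sp <- mirror_to_left(sp)
  raw <- resample_curves(sp, sch)
  raw2 <- sweep(3.1 * raw %*% rot2(0.9), 2, c(50, -20), `+`)
  out <- predict_unknown(fit, pca, raw2)
  expect_identical(as.character(out$group), st$specimens[[5]]$taxon)
  expect_gt(out$posterior, 0.5)
  post <- attr(out, "posterior")
  expect_equal(rowSums(post), 1, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(predict_unknown(fit, pca, raw[-1, ]), "points")
})

test_that("predict posteriors follow exp(-D^2/2) exactly", {
  d <- make_groups(n_per = 10, sep = 4, m = 3, seed = 86)
  fit <- cva(d$X, d$g)
  newdata <- d$X[c(3, 17, 25), ]
  pr <- predict(fit, newdata)
  want <- exp(-pr$mahalanobis_sq / 2)
  want <- want / rowSums(want)
  expect_equal(unname(pr$posterior), unname(want), tolerance = 1e-12)
  ## row at a group mean in score space is assigned to that group
  mean_b <- colMeans(d$X[d$g == "b", ])
  prb <- predict(fit, matrix(mean_b, 1))
  expect_identical(as.character(prb$class), "b")
  expect_equal(which.max(prb$posterior[1, ]), which.min(prb$mahalanobis_sq[1, ]))
})

test_that("shape_along_axis: consensus at score 0, linear in score, PCA slope = eigenvector", {
  sch <- tiny_scheme()
  st <- fixture_study(seed = 87, scheme = sch)
  al <- align_study(st, scheme = sch, slide = FALSE)
  pca <- shape_pca(al$joint$shapes)
  s0 <- shape_along_axis(pca, axis = 1, score = 0)
  expect_equal(s0, equimorph:::unflatten_config(colMeans(al$joint$shapes)),
               tolerance = 1e-12)
  s1 <- shape_along_axis(pca, axis = 1, score = 0.05)
  s2 <- shape_along_axis(pca, axis = 1, score = 0.10)
  expect_equal(s2 - s0, 2 * (s1 - s0), tolerance = 1e-10)

  ## least-squares oracle: slope of coords on PC1 scores equals the eigenvector
  sc1 <- pca$scores[, 1]
  slope <- as.vector(crossprod(sweep(al$joint$shapes, 2, pca$mean), sc1) / sum(sc1^2))
  expect_equal(slope, unname(pca$vectors[, 1]), tolerance = 1e-8)

  ## CVA variant returns the consensus at score 0 too
  g <- factor(al$meta$taxon)
  fit <- cva(retained_scores(pca), g)
  c0 <- shape_along_axis(fit, axis = 1, score = 0, coords = al$joint$shapes)
  expect_equal(c0, s0, tolerance = 1e-12)
})
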