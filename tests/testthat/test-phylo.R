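test_that("newick reading enforces branch lengths and round-trips", {
  tr <- read_tree(text = "((A:1,B:1):1,C:2);")
  expect_identical(sort(tr$tip.label), c("A", "B", "C"))
  expect_identical(length(tr$tip.label), 3L)

  expect_error(read_tree(text = "((A,B),C);"), "branch lengths")
  tr_unit <- read_tree(text = "((A,B),C);", unit_lengths = TRUE)
  expect_true(all(tr_unit$edge.length == 1))

  tf <- withr::local_tempfile(fileext = ".nwk")
  tr10 <- random_tree(10, seed = 91)
  ape::write.tree(tr10, tf)
  back <- read_tree(tf)
  expect_identical(back$tip.label, tr10$tip.label)
  expect_equal(back$edge.length, tr10$edge.length, tolerance = 1e-8)
})

test_that("phylogenetic covariance equals shared path lengths (path-sum oracle)", {
  tr <- read_tree(text = "((A:1,B:1):1,C:2);")
  C <- phylo_covariance(tr)
  expect_equal(C["A", "B"], 1)
  expect_equal(C["A", "A"], 2)
  expect_equal(C["A", "C"], 0)

  ## star tree with unit branches: identity
  star <- read_tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(unname(phylo_covariance(star)), diag(4), tolerance = 1e-12)

  ## random 6-tip tree vs brute-force path-sum oracle
  tr6 <- random_tree(6, seed = 92)
  expect_equal(phylo_covariance(tr6),
               vcv_path_oracle(tr6)[tr6$tip.label, tr6$tip.label],
               tolerance = 1e-10)

  ## ultrametric tree: constant diagonal
  ul <- ape::compute.brlen(random_tree(8, seed = 93), method = "Grafen")
  Cu <- phylo_covariance(ul)
  expect_lt(diff(range(diag(Cu))), 1e-8)
})

test_that("univariate kmult equals Blomberg's K from the direct formula", {
  for (i in 1:10) {
    tr <- random_tree(8, seed = 100 + i)
    y <- equimorph:::with_seed(200 + i, stats::setNames(rnorm(8), tr$tip.label))
    got <- kmult(matrix(y, ncol = 1, dimnames = list(names(y), NULL)),
                 tr, n_perm = 0)$K
    expect_equal(got, blomberg_k_oracle(y, tr), tolerance = 1e-10)
  }
})

test_that("kmult guards: identical rows error, zero-variance columns dropped, tip intersection", {
  tr <- random_tree(6, seed = 94)
  Y <- matrix(1, 6, 3, dimnames = list(tr$tip.label, NULL))
  expect_error(kmult(Y, tr), "zero variance")

  Y2 <- equimorph:::with_seed(95, matrix(rnorm(18), 6, 3,
                                         dimnames = list(tr$tip.label, NULL)))
  Y2[, 2] <- 5
  expect_warning(k2 <- kmult(Y2, tr, n_perm = 9, seed = 1), "zero-variance")

  ## extra species in the data are intersected away
  Y3 <- rbind(Y2[, c(1, 3)], extra = c(0, 0))
  expect_message(k3 <- kmult(Y3, tr, n_perm = 9, seed = 1), "common")
  expect_equal(k3$K, k2$K, tolerance = 1e-12)
})

test_that("kmult is invariant to orthogonal rotation of the trait columns", {
  tr <- random_tree(9, seed = 96)
  Y <- simulate_bm_means(tr, template = 0, rate = 1, d = 6, seed = 97)
  Q <- qr.Q(qr(equimorph:::with_seed(98, matrix(rnorm(36), 6, 6))))
  k1 <- kmult(Y, tr, n_perm = 0)$K
  k2 <- kmult(Y %*% Q, tr, n_perm = 0)$K
  expect_equal(k1, k2, tolerance = 1e-8)
})

test_that("kmult permutation p-value: add-one convention and calibration under the null", {
  tr <- random_tree(8, seed = 99)
  Y <- simulate_bm_means(tr, template = 0, rate = 1, d = 4, seed = 100)
  k <- kmult(Y, tr, n_perm = 99, seed = 7)
  expect_equal(k$p, (1 + sum(k$perm >= k$K)) / (k$n_perm + 1), tolerance = 1e-12)
  expect_identical(length(k$perm), 99L)

  ## iid tips (no phylogenetic structure): K tends below 1, test is calibrated
  set.seed(101)
  tr10 <- random_tree(10, seed = 102)
  ks <- replicate(60, {
    Y0 <- matrix(rnorm(10 * 5), 10, 5, dimnames = list(tr10$tip.label, NULL))
    kmult(Y0, tr10, n_perm = 0)$K
  })
  expect_lt(mean(ks), 1)
})

test_that("squared-change parsimony: closed forms, constant field, optimizer oracle", {
  ## two tips: root = inverse-branch-length weighted mean
  tr2 <- read_tree(text = "(A:2,B:0.5);")
  Y2 <- matrix(c(1, 4), 2, 1, dimnames = list(c("A", "B"), NULL))
  anc2 <- squared_change_parsimony(tr2, Y2)
  expect_equal(unname(anc2$node_values[1, 1]),
               (1 / 2 + 4 / 0.5) / (1 / 2 + 1 / 0.5), tolerance = 1e-12)

  ## constant tip values propagate unchanged to every node
  tr <- random_tree(7, seed = 103)
  Yc <- matrix(3.3, 7, 2, dimnames = list(tr$tip.label, NULL))
  ancc <- squared_change_parsimony(tr, Yc)
  expect_lt(max(abs(ancc$node_values - 3.3)), 1e-10)

  ## random 5-tip tree: objective matches a general-purpose numeric minimizer
  tr5 <- random_tree(5, seed = 104)
  Y5 <- equimorph:::with_seed(105, matrix(rnorm(5), 5, 1,
                                          dimnames = list(tr5$tip.label, NULL)))
  anc5 <- squared_change_parsimony(tr5, Y5)
  obj <- function(v) {
    states <- c(Y5[tr5$tip.label, 1], v)
    sum((states[tr5$edge[, 1]] - states[tr5$edge[, 2]])^2 / tr5$edge.length)
  }
  opt <- optim(rep(mean(Y5), tr5$Nnode), obj, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  expect_equal(anc5$objective, opt$value, tolerance = 1e-6)
  expect_equal(unname(anc5$node_values[, 1]), opt$par, tolerance = 1e-4)
})

test_that("SCP root equals the GLS (ML-under-BM) root estimate", {
  for (i in 1:10) {
    tr <- random_tree(6, seed = 300 + i)
    Y <- simulate_bm_means(tr, template = 0, rate = 1, d = 3, seed = 400 + i)
    anc <- squared_change_parsimony(tr, Y)
    C <- phylo_covariance(tr)
    Ci <- solve(C)
    gls_root <- colSums(Ci %*% Y[rownames(C), ]) / sum(Ci)
    expect_equal(unname(anc$node_values[1, ]), unname(gls_root), tolerance = 1e-8)
  }
})

test_that("phylomorphospace places nodes at SCP estimates in the retained PC space", {
  tr <- random_tree(8, seed = 106)
  means <- simulate_bm_means(tr, template = rnorm(12), rate = 0.4, seed = 107)
  pms <- phylomorphospace(means, tr)
  sc <- retained_scores(pms$pca)
  rownames(sc) <- rownames(means)[match(rownames(pms$tip_coords), rownames(means))]
  anc <- squared_change_parsimony(pms$tree, pms$tip_coords)
  expect_equal(pms$node_coords, anc$node_values, tolerance = 1e-10)
  ## root shape reconstruction lies in the PCA model space
  expect_identical(dim(pms$root_shape), c(6L, 2L))
  ## segments join parent/child coordinates
  all_xy <- rbind(pms$tip_coords, pms$node_coords)
  expect_equal(pms$segments$x0, unname(all_xy[pms$tree$edge[, 1], 1]),
               tolerance = 1e-12)
})

test_that("sister tips are shape neighbours under strong Brownian signal", {
  ## balanced 6-tip tree with long shared internal branches: in most BM draws
  ## the two cherries' tips end up mutual nearest neighbours on PC1/PC2
  tr <- read_tree(text = "(((A:0.2,B:0.2):2,(C:0.2,D:0.2):2):1,(E:0.2,F:0.2):2.6);")
  hits <- 0
  for (i in 1:100) {
    Y <- simulate_bm_means(tr, template = 0, rate = 1, d = 10, seed = 500 + i)
    pms <- phylomorphospace(Y, tr)
    xy <- pms$tip_coords[, 1:2]
    nn <- apply(as.matrix(dist(xy)) + diag(Inf, 6), 1, which.min)
    pairs <- list(c("A", "B"), c("C", "D"), c("E", "F"))
    ok <- all(vapply(pairs, function(pr) {
      i1 <- which(rownames(xy) == pr[1]); i2 <- which(rownames(xy) == pr[2])
      nn[i1] == i2 && nn[i2] == i1
    }, TRUE))
    hits <- hits + ok
  }
  expect_gte(hits / 100, 0.8)
})
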