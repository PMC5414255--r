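## shared fixtures: all data built in code, seeded

tiny_scheme <- function() slider_scheme(c(3L, 3L, 3L, 3L, 3L, 3L, 4L, 4L))

## a random rooted tree with positive branch lengths
random_tree <- function(n, seed = NULL) {
  equimorph:::with_seed(seed, {
    tr <- ape::rtree(n)
    tr$edge.length <- tr$edge.length + 0.1
    tr
  })
}

## independent path-sum oracle for the BM covariance: C[i,j] = summed length
## of edges shared by the root-to-tip paths of i and j
vcv_path_oracle <- function(tree) {
  N <- length(tree$tip.label)
  root <- N + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    parent[tree$edge[k, 2L]] <- tree$edge[k, 1L]
    elen[tree$edge[k, 2L]] <- tree$edge.length[k]
  }
  path_edges <- function(tip) {
    v <- tip; out <- integer(0)
    while (v != root) { out <- c(out, v); v <- parent[v] }
    out
  }
  paths <- lapply(seq_len(N), path_edges)
  C <- matrix(0, N, N, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(N)) for (j in seq_len(N))
    C[i, j] <- sum(elen[intersect(paths[[i]], paths[[j]])])
  C
}

## independent univariate Blomberg's K formula (direct, solve()-based)
blomberg_k_oracle <- function(y, tree) {
  C <- ape::vcv(tree)[names(y), names(y)]
  N <- length(y)
  Ci <- solve(C)
  one <- rep(1, N)
  a <- as.numeric((t(one) %*% Ci %*% y) / (t(one) %*% Ci %*% one))
  r <- y - a
  mse0 <- sum(r^2) / (N - 1)
  mse <- as.numeric(t(r) %*% Ci %*% r) / (N - 1)
  expected <- (sum(diag(C)) - N / sum(Ci)) / (N - 1)
  (mse0 / mse) / expected
}

## simple right triangle and friends for GPA toys
triangle <- function() matrix(c(0, 0, 1, 0, 0, 2), ncol = 2, byrow = TRUE)

rot2 <- function(theta) matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)

## a deterministic blobby configuration of p points (seeded)
random_config <- function(p, seed) {
  equimorph:::with_seed(seed, matrix(rnorm(2 * p), ncol = 2))
}
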