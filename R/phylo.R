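#' Read a rooted phylogeny with branch lengths
#'
#' Wrapper over [ape::read.tree()] that enforces the requirements of the
#' comparative methods in this package: unique tip labels and branch lengths
#' (both the Brownian-motion covariance and squared-change parsimony need
#' them). Polytomies are allowed.
#'
#' @param path path to a newick file (or a newick string via `text`).
#' @param text optional newick string instead of a file.
#' @param unit_lengths if `TRUE`, a tree without branch lengths is accepted
#'   and every branch set to 1.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_tree <- function(path = NULL, text = NULL, unit_lengths = FALSE) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse newick input")
  if (anyDuplicated(tree$tip.label)) stop("duplicated tip labels in tree")
  if (is.null(tree$edge.length)) {
    if (!unit_lengths)
      stop("tree has no branch lengths (required); set unit_lengths = TRUE to assume 1")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  tree
}

#' Brownian-motion phylogenetic covariance matrix
#'
#' Under Brownian motion, the expected covariance between trait values at two
#' tips is the shared root-to-MRCA path length, and the variance at a tip is
#' its root-to-tip path length. Computed with [ape::vcv()].
#'
#' @param tree a `phylo` object with branch lengths.
#' @return symmetric PSD `N x N` matrix, rows/cols in `tree$tip.label` order.
#' @export
phylo_covariance <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  C <- ape::vcv(tree)
  C[tree$tip.label, tree$tip.label]
}

## K statistic machinery shared between the observed value and permutations:
## precompute everything that depends only on the tree
kmult_prep <- function(C) {
  N <- nrow(C)
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < max(e$values) * 1e-12)
    stop("singular phylogenetic covariance (zero-length terminal structure?)")
  Cinv <- e$vectors %*% (t(e$vectors) / e$values)
  Cisqrt <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  ones <- rep(1, N)
  denom_expected <- (sum(diag(C)) - N / sum(Cinv)) / (N - 1)
  list(N = N, Cinv = Cinv, Cisqrt = Cisqrt, ones = ones,
       denom_expected = denom_expected)
}

kmult_stat <- function(Y, prep) {
  a <- colSums(prep$Cinv %*% Y) / sum(prep$Cinv)   # GLS phylogenetic mean
  R <- sweep(Y, 2L, a)
  num <- sum(R^2)
  den <- sum((prep$Cisqrt %*% R)^2)
  if (den == 0) stop("degenerate data: no variation after phylogenetic transform")
  (num / den) / prep$denom_expected
}

#' Multivariate phylogenetic signal (K statistic)
#'
#' The multivariate generalization of Blomberg's K: the ratio of the mean
#' squared tip deviation from the GLS phylogenetic mean in the original space
#' to the same quantity in the phylogenetically transformed space
#' (`C^-1/2`-whitened), scaled by its expectation under Brownian motion,
#' `(tr(C) - N / sum(C^-1)) / (N - 1)`. Under Brownian motion the expected
#' value is 1.0; values below 1 indicate less phylogenetic structure than
#' Brownian motion predicts. With a single trait column this reduces exactly
#' to the univariate K. Significance is assessed by permuting the rows of `Y`
#' (species identities) across the tips of the tree.
#'
#' @param Y `N x d` matrix of species mean traits (e.g. mean Procrustes
#'   coordinates or PC scores); rownames must be tip labels. Species absent
#'   from the tree (or tips absent from `Y`) are dropped with a message.
#' @param tree a `phylo` object with branch lengths.
#' @param n_perm number of permutations for the significance test.
#' @param seed integer seed for the permutations.
#' @return Object of class `kmult`: `K` (observed), `p` (add-one permutation
#'   p-value, `(1 + #{K_perm >= K_obs}) / (n_perm + 1)`), `perm` (the
#'   permutation distribution), `n_perm`, `seed`, `n_species`.
#' @export
kmult <- function(Y, tree, n_perm = 1000L, seed = NULL) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) stop("Y needs species rownames matching tip labels")
  common <- intersect(tree$tip.label, rownames(Y))
  if (length(common) < 3L) stop("fewer than 3 species shared between data and tree")
  if (length(common) < length(tree$tip.label) || length(common) < nrow(Y))
    message("kmult: using ", length(common), " species common to data and tree")
  tree <- ape::keep.tip(tree, common)
  Y <- Y[tree$tip.label, , drop = FALSE]

  v <- apply(Y, 2L, stats::var)
  if (all(v == 0)) stop("all trait columns have zero variance across species")
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance trait column(s) dropped")
    Y <- Y[, v > 0, drop = FALSE]
  }

  prep <- kmult_prep(phylo_covariance(tree))
  K_obs <- kmult_stat(Y, prep)
  perm <- numeric(n_perm)
  with_seed(seed, {
    for (b in seq_len(n_perm))
      perm[b] <- kmult_stat(Y[sample.int(nrow(Y)), , drop = FALSE], prep)
  })
  p <- (1 + sum(perm >= K_obs)) / (n_perm + 1)
  structure(list(K = K_obs, p = p, perm = perm, n_perm = n_perm, seed = seed,
                 n_species = nrow(Y)),
            class = "kmult")
}

#' @export
print.kmult <- function(x, ...) {
  cat(sprintf("Multivariate phylogenetic signal: K = %.4f, p = %.4g (%d permutations, %d species)\n",
              x$K, x$p, x$n_perm, x$n_species))
  invisible(x)
}

#' @export
plot.kmult <- function(x, ...) {
  graphics::hist(x$perm, breaks = 30, main = "Permutation distribution of K",
                 xlab = "K", col = "grey85", border = "grey50",
                 xlim = range(c(x$perm, x$K)), ...)
  graphics::abline(v = x$K, col = "red", lwd = 2)
  invisible(x)
}

#' Squared-change parsimony ancestral states
#'
#' Estimates trait values at the internal nodes (including the root) that
#' minimize the sum of squared changes along branches, each change weighted by
#' the inverse branch length: `sum_edges ||x_parent - x_child||^2 / length`.
#' The stationarity conditions make every internal node the
#' inverse-branch-length-weighted average of its neighbours, a sparse linear
#' system solved exactly per trait dimension. Tips are fixed at their observed
#' values. With branch lengths, these estimates coincide with
#' maximum-likelihood (GLS) ancestral estimates under Brownian motion.
#'
#' @param tree a `phylo` object with positive branch lengths (zero-length
#'   branches are floored to a small value with a warning).
#' @param Y `N x d` matrix of tip values, rownames = tip labels (species are
#'   intersected with the tree as in [kmult()]).
#' @return Object of class `ancestral_shapes`: `node_values`
#'   (`n_internal x d`, rownames = internal node numbers, root first row is
#'   node `N+1`), `tip_values`, `edges` (the tree edge matrix), `tree`,
#'   `objective` (the minimized weighted sum of squared changes).
#' @export
squared_change_parsimony <- function(tree, Y) {
  Y <- as.matrix(Y)
  if (is.null(rownames(Y))) stop("Y needs species rownames matching tip labels")
  common <- intersect(tree$tip.label, rownames(Y))
  if (length(common) < 2L) stop("fewer than 2 species shared between data and tree")
  if (length(common) < length(tree$tip.label) || length(common) < nrow(Y))
    message("squared_change_parsimony: using ", length(common), " shared species")
  tree <- ape::keep.tip(tree, common)
  Y <- Y[tree$tip.label, , drop = FALSE]

  N <- length(tree$tip.label)
  M <- tree$Nnode
  edge <- tree$edge
  len <- tree$edge.length
  if (is.null(len)) stop("tree has no branch lengths")
  if (any(len <= 0)) {
    warning("zero-length branch(es) floored to 1e-8 of tree depth")
    len[len <= 0] <- 1e-8 * max(ape::node.depth.edgelength(tree))
  }
  w <- 1 / len

  ## weighted graph Laplacian over all nodes, partitioned into internal (free)
  ## and tip (fixed) blocks
  n_all <- N + M
  A <- matrix(0, n_all, n_all)
  for (k in seq_len(nrow(edge))) {
    i <- edge[k, 1L]; j <- edge[k, 2L]
    A[i, j] <- A[i, j] + w[k]
    A[j, i] <- A[j, i] + w[k]
  }
  Dg <- diag(rowSums(A))
  L <- Dg - A
  int <- (N + 1L):n_all
  tip <- seq_len(N)
  X_int <- solve(L[int, int, drop = FALSE],
                 -L[int, tip, drop = FALSE] %*% Y)
  rownames(X_int) <- as.character(int)

  all_states <- rbind(Y, X_int)
  d_edges <- all_states[edge[, 1L], , drop = FALSE] -
             all_states[edge[, 2L], , drop = FALSE]
  objective <- sum(rowSums(d_edges^2) * w)

  structure(list(node_values = X_int, tip_values = Y, edges = edge,
                 tree = tree, objective = objective),
            class = "ancestral_shapes")
}

#' @export
print.ancestral_shapes <- function(x, ...) {
  cat("Squared-change parsimony reconstruction:", nrow(x$node_values),
      "internal nodes,", ncol(x$node_values), "trait dimensions\n",
      " weighted sum of squared changes:", format(x$objective, digits = 6), "\n")
  invisible(x)
}

#' Phylomorphospace projection
#'
#' Projects a phylogeny into the shape ordination space of species mean
#' shapes: a PCA of the mean Procrustes coordinates gives the ordination,
#' squared-change parsimony places the internal nodes (including the root) in
#' the retained score space, and the tree branches become segments joining
#' tip and node coordinates. Also returns the reconstructed root shape and the
#' per-species shape configurations so species outlines can be drawn against
#' the ancestral outline.
#'
#' @param means `N x 2p` matrix of species mean Procrustes coordinates
#'   (rownames = taxon codes / tip labels), typically from a species-mean GPA.
#' @param tree a `phylo` object with branch lengths over (a superset of) the
#'   species.
#' @param threshold PCA variance-retention threshold passed to [shape_pca()].
#' @return Object of class `phylomorphospace`: `tip_coords` and `node_coords`
#'   (scores on the retained PCs, first two used for plotting), `segments`
#'   (data frame of edge endpoints on PC1/PC2), `pca`, `anc` (the
#'   [squared_change_parsimony()] fit in score space), `root_shape` and
#'   `tip_shapes` (`p x 2` configurations), `shape_vs_root` (list of per-
#'   species displacement fields from the root outline), `tree`.
#' @export
phylomorphospace <- function(means, tree, threshold = 0.99) {
  means <- as.matrix(means)
  if (is.null(rownames(means))) stop("means needs taxon rownames")
  common <- intersect(tree$tip.label, rownames(means))
  if (length(common) < 3L) stop("fewer than 3 species shared between data and tree")
  tree <- ape::keep.tip(tree, common)
  means <- means[tree$tip.label, , drop = FALSE]

  pca <- shape_pca(means, threshold = threshold)
  pca$retained <- min(max(pca$retained, 2L), length(pca$eigenvalues))  # need 2 axes to draw
  sc <- retained_scores(pca)
  rownames(sc) <- rownames(means)
  anc <- squared_change_parsimony(tree, sc)

  N <- length(tree$tip.label)
  all_xy <- rbind(sc, anc$node_values)
  edge <- tree$edge
  segments <- data.frame(
    x0 = all_xy[edge[, 1L], 1L], y0 = all_xy[edge[, 1L], 2L],
    x1 = all_xy[edge[, 2L], 1L], y1 = all_xy[edge[, 2L], 2L])

  root_score <- anc$node_values[1L, ]   # node N+1 is the root in ape numbering
  root_flat <- pca$mean +
    as.vector(pca$vectors[, seq_len(pca$retained), drop = FALSE] %*% root_score)
  root_shape <- unflatten_config(root_flat)
  tip_shapes <- lapply(seq_len(N), function(i) unflatten_config(means[i, ]))
  names(tip_shapes) <- tree$tip.label
  shape_vs_root <- lapply(tip_shapes, function(s) s - root_shape)

  structure(list(tip_coords = sc, node_coords = anc$node_values,
                 segments = segments, pca = pca, anc = anc,
                 root_shape = root_shape, tip_shapes = tip_shapes,
                 shape_vs_root = shape_vs_root, tree = tree),
            class = "phylomorphospace")
}

#' @export
print.phylomorphospace <- function(x, ...) {
  cat("Phylomorphospace:", nrow(x$tip_coords), "species,",
      nrow(x$node_coords), "internal nodes on", x$pca$retained, "retained PCs\n")
  invisible(x)
}

#' @export
plot.phylomorphospace <- function(x, ...) {
  xy <- rbind(x$tip_coords[, 1:2, drop = FALSE], x$node_coords[, 1:2, drop = FALSE])
  plot(xy, type = "n", xlab = "PC1", ylab = "PC2", asp = 1, ...)
  graphics::segments(x$segments$x0, x$segments$y0, x$segments$x1, x$segments$y1,
                     col = "grey60")
  graphics::points(x$node_coords[, 1:2, drop = FALSE], pch = 21, bg = "white", cex = 0.8)
  graphics::points(x$tip_coords[, 1:2, drop = FALSE], pch = 16, col = "steelblue")
  graphics::text(x$tip_coords[, 1:2, drop = FALSE], labels = rownames(x$tip_coords),
                 pos = 3, cex = 0.7)
  invisible(x)
}
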