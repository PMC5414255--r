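#' Principal component analysis of shape coordinates
#'
#' Eigendecomposition of the covariance of Procrustes coordinates (or any
#' numeric trait matrix). Dimensionality for downstream discriminant analyses
#' is reduced by keeping the smallest number of components whose cumulative
#' variance fraction reaches `threshold` (default 99% of total shape
#' variance).
#'
#' @param x a `gpa_fit` or an `n x k` numeric matrix (rows = specimens).
#' @param threshold cumulative variance fraction to retain, in (0, 1].
#' @return Object of class `shape_pca`: `mean` (length-k vector),
#'   `eigenvalues` (all, non-increasing), `vectors` (k x r orthonormal),
#'   `scores` (n x r, zero column means), `retained` (number of components at
#'   `threshold`), `threshold`, `total_variance`.
#' @export
shape_pca <- function(x, threshold = 0.99) {
  X <- if (inherits(x, "gpa_fit")) x$shapes else as.matrix(x)
  n <- nrow(X)
  if (n < 3L) stop("PCA needs at least 3 specimens")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  total <- sum(Xc^2) / (n - 1)
  if (total <= 0) stop("zero total variance: all shapes identical")
  s <- svd(Xc)
  ev <- s$d^2 / (n - 1)
  keep <- ev > max(ev) * 1e-12
  ev <- ev[keep]
  vectors <- s$v[, keep, drop = FALSE]
  scores <- Xc %*% vectors
  cum <- cumsum(ev) / total
  retained <- which(cum >= threshold - 1e-12)[1L]
  if (is.na(retained)) retained <- length(ev)
  colnames(scores) <- colnames(vectors) <- paste0("PC", seq_along(ev))
  structure(list(mean = mu, eigenvalues = ev, vectors = vectors,
                 scores = scores, retained = retained, threshold = threshold,
                 total_variance = total),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cum <- cumsum(x$eigenvalues) / x$total_variance
  cat("Shape PCA:", length(x$eigenvalues), "components;",
      x$retained, "retained at", paste0(100 * x$threshold, "%"),
      "cumulative variance\n")
  k <- min(5L, length(x$eigenvalues))
  tab <- rbind(`prop. var` = x$eigenvalues[1:k] / x$total_variance,
               `cumulative` = cum[1:k])
  colnames(tab) <- paste0("PC", 1:k)
  print(round(tab, 4))
  invisible(x)
}

#' @export
predict.shape_pca <- function(object, newdata, retained_only = TRUE, ...) {
  nd <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  sc <- sweep(nd, 2L, object$mean) %*% object$vectors
  if (retained_only) sc <- sc[, seq_len(object$retained), drop = FALSE]
  sc
}

#' Retained PC scores
#'
#' @param pca a [shape_pca] fit.
#' @return the score matrix restricted to the retained components.
#' @export
retained_scores <- function(pca) {
  pca$scores[, seq_len(pca$retained), drop = FALSE]
}

#' Model shape along an ordination or discriminant axis
#'
#' Visualization helper: regresses the original coordinates on the scores of
#' one axis and returns the modelled shape `mean + score * slope`, reshaped to
#' a `p x 2` configuration. At `score = 0` this is exactly the consensus
#' (mean) shape. For a PCA axis the regression slope equals the eigenvector,
#' so this reduces to the usual shape reconstruction along a PC.
#'
#' @param object a [shape_pca] or [cva] fit.
#' @param axis axis index.
#' @param score position along the axis (in score units).
#' @param coords for a `cva_fit`, the `n x 2p` coordinate matrix the analysis
#'   was derived from (needed to regress coordinates on canonical scores).
#' @return `p x 2` configuration matrix.
#' @export
shape_along_axis <- function(object, axis = 1L, score = 0, coords = NULL) {
  UseMethod("shape_along_axis")
}

#' @export
shape_along_axis.shape_pca <- function(object, axis = 1L, score = 0, coords = NULL) {
  if (axis < 1L || axis > ncol(object$vectors)) stop("no such axis: ", axis)
  v <- object$mean + score * object$vectors[, axis]
  matrix(v, ncol = 2L, byrow = TRUE)
}

#' @export
shape_along_axis.cva_fit <- function(object, axis = 1L, score = 0, coords = NULL) {
  if (is.null(coords)) stop("supply the coordinate matrix used to build the CVA")
  if (axis < 1L || axis > ncol(object$scores)) stop("no such axis: ", axis)
  s <- object$scores[, axis]
  sc <- s - mean(s)
  slope <- crossprod(sweep(as.matrix(coords), 2L, colMeans(coords)), sc) / sum(sc^2)
  v <- colMeans(coords) + score * as.vector(slope)
  matrix(v, ncol = 2L, byrow = TRUE)
}
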