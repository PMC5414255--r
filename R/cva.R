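## minimal CVA core used both by the user-facing fit and inside the
## cross-validation rounds; assumes validated inputs. Solves the generalized
## eigenproblem max a'Ba s.t. a'Wa = 1 via the Cholesky factor of W.
cva_core <- function(scores, groups) {
  groups <- droplevels(factor(groups))
  g <- nlevels(groups)
  n <- nrow(scores)
  m <- ncol(scores)
  grand <- colMeans(scores)
  means <- rowsum(scores, groups) / as.vector(table(groups))
  Xw <- scores - means[groups, , drop = FALSE]
  W <- crossprod(Xw) / (n - g)
  dm <- sweep(means, 2L, grand)
  B <- crossprod(dm * sqrt(as.vector(table(groups)))) / (g - 1)
  U <- chol(W)                         # W = U'U; fails if W singular
  Tm <- backsolve(U, diag(m))          # U^{-1}
  S <- crossprod(Tm, B) %*% Tm         # T' B T, symmetric
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  r <- min(g - 1L, m)
  axes <- Tm %*% e$vectors[, seq_len(r), drop = FALSE]
  colnames(axes) <- paste0("CV", seq_len(r))
  centroids <- sweep(means, 2L, grand) %*% axes
  list(axes = axes, eigenvalues = e$values[seq_len(r)], grand = grand,
       centroids = centroids, groups = levels(groups))
}

#' Canonical variate analysis
#'
#' Computes the discriminant axes of variation among groups: the eigenvectors
#' of `W^-1 B` (pooled within-group vs between-group covariance), scaled so
#' that each canonical variate has unit pooled within-group variance. This
#' builds the "discriminant shape space" in which group differences are
#' expressed in Mahalanobis units. Run on PC scores retained at a variance
#' threshold (see [shape_pca()]) so that `W` is invertible.
#'
#' @param scores `n x m` numeric score matrix.
#' @param groups grouping factor; every group needs at least 2 members.
#' @return Object of class `cva_fit`: `axes` (m x r, r = min(groups-1, m)),
#'   `eigenvalues`, `grand_mean`, `centroids` (group means in canonical
#'   space), `scores` (n x r canonical variates), `groups` (factor),
#'   `group_levels`.
#' @export
cva <- function(scores, groups) {
  scores <- as.matrix(scores)
  groups <- droplevels(factor(groups))
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("group(s) with a single specimen: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  core <- tryCatch(cva_core(scores, groups), error = function(e)
    stop("pooled within-group covariance is singular; retain fewer PCs (",
         conditionMessage(e), ")"))
  cv_scores <- sweep(scores, 2L, core$grand) %*% core$axes
  structure(c(core, list(scores = cv_scores, group_factor = groups)),
            class = "cva_fit")
}

#' @export
print.cva_fit <- function(x, ...) {
  cat("Canonical variate analysis:", length(x$groups), "groups,",
      ncol(x$axes), "canonical axes\n  eigenvalues:",
      paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.cva_fit <- function(x, axes = c(1L, 2L), ...) {
  if (ncol(x$scores) < 2L) stop("need at least two canonical axes to plot")
  cols <- as.integer(x$group_factor)
  plot(x$scores[, axes], col = cols, pch = 16, asp = 1,
       xlab = paste0("CV", axes[1L]), ylab = paste0("CV", axes[2L]), ...)
  graphics::points(x$centroids[, axes], pch = 3, cex = 1.2)
  invisible(x)
}

## assign rows of canonical-space coordinates to the nearest group centroid;
## Euclidean distance in canonical space = Mahalanobis distance in score space
assign_canonical <- function(z, centroids) {
  d2 <- outer(rowSums(z^2), rowSums(centroids^2), "+") - 2 * z %*% t(centroids)
  d2[d2 < 0] <- 0
  cls <- apply(d2, 1L, which.min)      # ties -> lowest group index
  list(class = cls, d2 = d2)
}

#' Predict group membership from a CVA fit
#'
#' Projects new score rows into canonical space and assigns each to the group
#' with minimum Mahalanobis distance (equal priors); posterior probabilities
#' are proportional to `exp(-D^2/2)`.
#'
#' @param object a [cva] fit.
#' @param newdata `n x m` matrix in the same score space the CVA was fitted on.
#' @param ... unused.
#' @return list with `class` (factor of assignments), `mahalanobis_sq`
#'   (`n x groups` squared distances) and `posterior` (`n x groups`, rows sum
#'   to 1).
#' @export
predict.cva_fit <- function(object, newdata, ...) {
  nd <- if (is.matrix(newdata)) newdata else matrix(newdata, nrow = 1L)
  z <- sweep(nd, 2L, object$grand) %*% object$axes
  asg <- assign_canonical(z, object$centroids)
  lw <- -asg$d2 / 2
  lw <- lw - apply(lw, 1L, max)
  post <- exp(lw) / rowSums(exp(lw))
  colnames(post) <- colnames(asg$d2) <- object$groups
  list(class = factor(object$groups[asg$class], levels = object$groups),
       mahalanobis_sq = asg$d2, posterior = post)
}

#' Twofold cross-validated classification
#'
#' Estimates practical identification accuracy by repeated stratified twofold
#' cross-validation: each round splits every group into a training and a
#' testing half (training size alternates between ceiling and floor of half
#' the group, never leaving either side empty, so a group of 2 contributes
#' 1 + 1), fits a CVA on the training rows, and assigns each testing row to
#' the group with minimum Mahalanobis distance in canonical space. Assignment
#' rates are aggregated per specimen over rounds.
#'
#' Two summaries are reported: `ccv` — the mean per-round percentage of
#' correct assignments (the headline correct cross-validation percentage) —
#' and `ccv_modal`, the percentage of specimens whose modal (most frequent)
#' cross-validated assignment is their true group.
#'
#' @param scores `n x m` score matrix.
#' @param groups grouping factor (every group `n >= 2`).
#' @param rounds number of cross-validation rounds.
#' @param seed integer seed for the partitions.
#' @return Object of class `classification_report`: `ccv`, `ccv_modal`,
#'   `ccv_per_group` (per-group mean assignment rate to the true group, %),
#'   `confusion` (groups x groups mean assignment rates, rows = true),
#'   `per_specimen` (data frame of per-group assignment rates), `rounds`,
#'   `seed`, `redraws`.
#' @export
crossval_classify <- function(scores, groups, rounds = 10000L, seed = NULL) {
  scores <- as.matrix(scores)
  groups <- droplevels(factor(groups))
  n <- nrow(scores)
  g <- nlevels(groups)
  sizes <- table(groups)
  if (any(sizes < 2L))
    stop("group(s) too small for twofold cross-validation: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  gidx <- split(seq_len(n), groups)

  assigned <- matrix(0, n, g, dimnames = list(rownames(scores), levels(groups)))
  tested <- numeric(n)
  round_correct <- numeric(rounds)
  redraws <- 0L

  with_seed(seed, {
    for (r in seq_len(rounds)) {
      repeat {
        train <- unlist(lapply(gidx, function(ix) {
          k <- length(ix)
          ntr <- if (r %% 2L == 1L) ceiling(k / 2) else floor(k / 2)
          ntr <- max(1L, min(ntr, k - 1L))
          sample(ix, ntr)
        }), use.names = FALSE)
        test <- setdiff(seq_len(n), train)
        core <- tryCatch(cva_core(scores[train, , drop = FALSE], groups[train]),
                         error = function(e) NULL)
        if (!is.null(core)) break
        redraws <- redraws + 1L
        if (redraws > rounds / 2)
          stop("more than half of the cross-validation splits were untrainable; ",
               "retain fewer PCs or merge tiny groups")
      }
      z <- sweep(scores[test, , drop = FALSE], 2L, core$grand) %*% core$axes
      asg <- assign_canonical(z, core$centroids)
      cls <- match(core$groups[asg$class], levels(groups))
      assigned[cbind(test, cls)] <- assigned[cbind(test, cls)] + 1
      tested[test] <- tested[test] + 1
      round_correct[r] <- mean(cls == as.integer(groups[test]))
    }
  })

  rates <- assigned / pmax(tested, 1)
  true_idx <- as.integer(groups)
  per_spec_correct <- rates[cbind(seq_len(n), true_idx)]
  modal <- max.col(rates, ties.method = "first")
  confusion <- rowsum(rates, groups) / as.vector(sizes)

  structure(list(
    ccv = 100 * mean(round_correct),
    ccv_modal = 100 * mean(modal == true_idx),
    ccv_per_group = 100 * as.vector(rowsum(per_spec_correct, groups) / as.vector(sizes)),
    confusion = confusion,
    per_specimen = data.frame(id = rownames(scores) %||% as.character(seq_len(n)),
                              group = groups, rate_correct = per_spec_correct,
                              rates, check.names = FALSE),
    rounds = rounds, seed = seed, redraws = redraws),
    class = "classification_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Cross-validated classification (%d rounds): CCV = %.2f%% (modal %.2f%%)\n",
              x$rounds, x$ccv, x$ccv_modal))
  cat("Per-group CCV (%):\n")
  pg <- round(x$ccv_per_group, 2)
  names(pg) <- rownames(x$confusion)
  print(pg)
  invisible(x)
}

#' Predictive assignment of undetermined specimens
#'
#' Assigns configurations of unknown group (e.g. isolated teeth) to the groups
#' of a trained discriminant model: each unknown is superimposed onto the
#' training consensus by a single orthogonal Procrustes fit, projected onto
#' the retained PCs, and classified by Mahalanobis distance in canonical
#' space, with posterior probabilities proportional to `exp(-D^2/2)`.
#'
#' @param model a [cva] fit built on `retained_scores(pca)`.
#' @param pca the [shape_pca] of the training Procrustes coordinates.
#' @param unknowns a single `p x 2` configuration or a list of them, already
#'   resampled to the training scheme (see [resample_curves()]).
#' @return data frame with the assigned `group` and maximum `posterior`, plus
#'   attributes `posterior` and `mahalanobis_sq` (full matrices).
#' @export
predict_unknown <- function(model, pca, unknowns) {
  if (is.matrix(unknowns)) unknowns <- list(unknowns)
  consensus <- unflatten_config(pca$mean)
  p <- nrow(consensus)
  rows <- lapply(unknowns, function(u) {
    u <- as.matrix(u)
    if (nrow(u) != p)
      stop("unknown has ", nrow(u), " points; training space has ", p)
    flatten_config(procrustes_align(u, consensus)$x)
  })
  X <- do.call(rbind, rows)
  sc <- predict(pca, X, retained_only = FALSE)
  sc <- sc[, seq_len(nrow(model$axes)), drop = FALSE]   # dims the CVA was trained on
  pr <- predict(model, sc)
  out <- data.frame(group = pr$class,
                    posterior = pr$posterior[cbind(seq_len(nrow(X)),
                                                   as.integer(pr$class))])
  attr(out, "posterior") <- pr$posterior
  attr(out, "mahalanobis_sq") <- pr$mahalanobis_sq
  out
}
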