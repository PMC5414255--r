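## center a configuration and scale it to unit centroid size
center_scale <- function(x) {
  x <- sweep(x, 2L, colMeans(x))
  x / sqrt(sum(x^2))
}

## optimal rotation-only (det +1) least-squares rotation of x onto y
opa_rotation <- function(x, y) {
  s <- svd(crossprod(x, y))
  R <- s$u %*% t(s$v)
  if (det(R) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    R <- u %*% t(s$v)
  }
  R
}

#' Two-configuration Procrustes alignment
#'
#' Centers and scales both configurations to unit centroid size, then rotates
#' `x` onto `y` by the rotation-only least-squares solution (no reflection).
#'
#' @param x,y numeric `p x 2` matrices with equal `p`.
#' @return list with the aligned `x`, the target `y` (centered/scaled), the
#'   rotation matrix and `distance`, the (partial) Procrustes distance
#'   `sqrt(sum((x_aligned - y)^2))`.
#' @export
procrustes_align <- function(x, y) {
  x <- center_scale(as.matrix(x))
  y <- center_scale(as.matrix(y))
  R <- opa_rotation(x, y)
  xr <- x %*% R
  list(x = xr, y = y, rotation = R, distance = sqrt(sum((xr - y)^2)))
}

## rotate the whole sample so the consensus lies along its principal axes,
## with a deterministic sign convention, making GPA output independent of the
## orientation in which configurations were digitized
orient_to_principal_axes <- function(coords, cons) {
  e <- eigen(crossprod(cons), symmetric = TRUE)
  R <- e$vectors
  if (det(R) < 0) R[, 2L] <- -R[, 2L]
  cons2 <- cons %*% R
  k <- which.max(abs(cons2[, 1L]))
  if (cons2[k, 1L] < 0) R <- -R          # rotate by pi, still det +1
  cons2 <- cons %*% R
  for (i in seq_len(dim(coords)[3L])) coords[, , i] <- coords[, , i] %*% R
  list(coords = coords, consensus = cons2)
}

#' Generalized Procrustes analysis with optional semi-landmark sliding
#'
#' Iterative least-squares superimposition: every configuration is centered,
#' scaled to unit centroid size and rotated (rotations only, no reflection —
#' side is assumed standardized by [mirror_to_left()]) onto the running
#' consensus, which is updated until it stabilizes. When `slide = TRUE`,
#' semi-landmarks are additionally slid along their local curve tangents to
#' minimize thin-plate-spline bending energy relative to the consensus
#' ([slide_semilandmarks()]); one full slide pass is interleaved per
#' GPA+slide cycle, then shapes are re-centered, re-scaled and re-rotated.
#' Finally the whole sample is rotated to the consensus' principal axes with a
#' fixed sign convention so that the output does not depend on the arbitrary
#' orientation of the input.
#'
#' @param configs list of `p x 2` matrices (all with equal `p`), or a
#'   `p x 2 x n` array.
#' @param scheme a [slider_scheme]; required when `slide = TRUE`.
#' @param slide logical; slide semi-landmarks by bending energy.
#' @param slide_cycles number of GPA+slide cycles when sliding.
#' @param max_iter maximum rotation iterations per cycle.
#' @param tol convergence tolerance on the consensus (root-mean-square change).
#' @return Object of class `gpa_fit`: list with `coords` (`p x 2 x n` array of
#'   Procrustes coordinates, each of unit centroid size), `shapes` (`n x 2p`
#'   row-flattened matrix, columns x1,y1,...,xp,yp), `centroid_sizes`,
#'   `consensus` (`p x 2`, the coordinate-wise mean shape), `scheme`, `slid`,
#'   `converged` and `iterations`.
#' @export
gpa <- function(configs, scheme = NULL, slide = FALSE, slide_cycles = 5L,
                max_iter = 100L, tol = 1e-10) {
  if (is.array(configs) && length(dim(configs)) == 3L)
    configs <- lapply(seq_len(dim(configs)[3L]), function(i) configs[, , i])
  n <- length(configs)
  if (n < 2L) stop("GPA needs at least two configurations")
  p <- nrow(configs[[1L]])
  if (any(vapply(configs, nrow, 0L) != p))
    stop("all configurations must have the same number of points")
  if (slide && is.null(scheme)) stop("sliding requires a slider scheme")

  csizes <- vapply(configs, centroid_size, 0)
  coords <- array(0, c(p, 2L, n))
  for (i in seq_len(n)) coords[, , i] <- center_scale(as.matrix(configs[[i]]))

  rotate_all <- function(coords, cons) {
    for (i in seq_len(dim(coords)[3L]))
      coords[, , i] <- coords[, , i] %*% opa_rotation(coords[, , i], cons)
    coords
  }
  mean_shape <- function(coords) apply(coords, c(1L, 2L), mean)

  converge_rotations <- function(coords, cons) {
    iters <- 0L
    converged <- FALSE
    repeat {
      coords <- rotate_all(coords, cons)
      new_cons <- mean_shape(coords)
      delta <- sqrt(mean((new_cons - cons)^2))
      cons <- new_cons
      iters <- iters + 1L
      if (delta < tol) { converged <- TRUE; break }
      if (iters >= max_iter) break
    }
    list(coords = coords, cons = cons, converged = converged, iters = iters)
  }

  st <- converge_rotations(coords, coords[, , 1L])
  total_iters <- st$iters
  converged <- st$converged

  if (slide) {
    for (cycle in seq_len(slide_cycles)) {
      ref <- center_scale(st$cons)
      bem <- bending_energy_model(ref)
      e_before <- 0; e_after <- 0
      for (i in seq_len(n)) {
        y <- st$coords[, , i]
        e_before <- e_before + bending_energy(bem, y)
        y <- slide_one(y, ref, bem$Lk, scheme)
        e_after <- e_after + bending_energy(bem, y)
        st$coords[, , i] <- center_scale(y)
      }
      st <- converge_rotations(st$coords, st$cons)
      total_iters <- total_iters + st$iters
      converged <- st$converged
      if (abs(e_before - e_after) < tol * max(1, e_before)) break
    }
  }

  orn <- orient_to_principal_axes(st$coords, st$cons)
  coords <- orn$coords
  cons <- mean_shape(coords)

  shapes <- t(apply(coords, 3L, function(m) as.vector(t(m))))
  colnames(shapes) <- paste0(rep(c("x", "y"), p), rep(seq_len(p), each = 2L))
  structure(list(coords = coords, shapes = shapes, centroid_sizes = csizes,
                 consensus = cons, scheme = scheme, slid = isTRUE(slide),
                 converged = converged, iterations = total_iters),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Generalized Procrustes fit:", dim(x$coords)[3L], "configurations of",
      dim(x$coords)[1L], "points;",
      if (x$slid) "semi-landmarks slid (bending energy)" else "no sliding",
      "\n  consensus centroid size:", format(sqrt(sum(center_scale(x$consensus)^2))),
      "; converged:", x$converged, "in", x$iterations, "iterations\n")
  invisible(x)
}

#' @export
plot.gpa_fit <- function(x, ...) {
  n <- dim(x$coords)[3L]
  plot(NA, xlim = range(x$coords[, 1L, ]), ylim = range(x$coords[, 2L, ]),
       asp = 1, xlab = "", ylab = "", main = "Procrustes coordinates", ...)
  for (i in seq_len(n))
    graphics::points(x$coords[, , i], pch = 16, cex = 0.3,
                     col = grDevices::grey(0.4, alpha = 0.4))
  graphics::points(x$consensus, pch = 21, bg = "tomato", cex = 0.7)
  invisible(x)
}

## --- thin-plate-spline bending energy ---------------------------------------

#' Thin-plate-spline bending energy model
#'
#' Assembles, for a 2D reference configuration, the bending-energy quadratic
#' form of the thin-plate spline: with kernel `U(r) = r^2 log(r^2)` the system
#' matrix `L = [[K, Q], [Q', 0]]` is built (`Q` the affine design `(1, x, y)`)
#' and the upper-left `p x p` block of `L^-1` is the bending-energy matrix
#' `Lk`. For any per-point displacement field `d` (one coordinate at a time),
#' `d' Lk d` is the bending energy of the interpolating spline; it vanishes
#' exactly on affine fields.
#'
#' @param reference numeric `p x 2` matrix; points must not be collinear.
#' @return Object of class `bending_energy`: list with `reference` and `Lk`
#'   (symmetrized `p x p` matrix).
#' @export
bending_energy_model <- function(reference) {
  x <- as.matrix(reference)
  p <- nrow(x)
  if (p < 4L) stop("bending energy needs at least 4 reference points")
  d2 <- as.matrix(stats::dist(x))^2
  K <- ifelse(d2 == 0, 0, d2 * log(d2))
  Q <- cbind(1, x)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3L, 3L)))
  Linv <- tryCatch(solve(L), error = function(e)
    stop("singular TPS system: reference points are collinear or coincident; ",
         "jitter the reference"))
  Lk <- Linv[seq_len(p), seq_len(p), drop = FALSE]
  Lk <- (Lk + t(Lk)) / 2
  structure(list(reference = x, Lk = Lk), class = "bending_energy")
}

#' Bending energy of a shape relative to the model reference
#'
#' @param model a [bending_energy_model()] fit.
#' @param shape numeric `p x 2` matrix.
#' @return non-negative scalar: `dx' Lk dx + dy' Lk dy` for the displacement
#'   `shape - reference`.
#' @export
bending_energy <- function(model, shape) {
  d <- as.matrix(shape) - model$reference
  as.numeric(t(d[, 1L]) %*% model$Lk %*% d[, 1L] +
             t(d[, 2L]) %*% model$Lk %*% d[, 2L])
}

## slide the semi-landmarks of one shape along local tangents so that the
## bending energy of (shape - reference) is minimized; tangents are the chords
## between each slider's neighbours in the current shape. Returns the slid
## shape (not re-centered/re-scaled).
slide_one <- function(y, ref, Lk, scheme) {
  sl <- scheme$sliders
  m <- nrow(sl)
  tang <- y[sl[, 3L], , drop = FALSE] - y[sl[, 1L], , drop = FALSE]
  len <- sqrt(rowSums(tang^2))
  ok <- len > 1e-12
  if (!all(ok)) warning(sum(!ok), " semi-landmark(s) with degenerate tangent held fixed")
  if (!any(ok)) return(y)
  tang <- tang[ok, , drop = FALSE] / len[ok]
  idx <- sl[ok, 2L]
  p <- nrow(y)
  mm <- sum(ok)
  Ux <- matrix(0, p, mm); Uy <- matrix(0, p, mm)
  Ux[cbind(idx, seq_len(mm))] <- tang[, 1L]
  Uy[cbind(idx, seq_len(mm))] <- tang[, 2L]
  dx <- y[, 1L] - ref[, 1L]
  dy <- y[, 2L] - ref[, 2L]
  LUx <- Lk %*% Ux; LUy <- Lk %*% Uy
  A <- crossprod(Ux, LUx) + crossprod(Uy, LUy)
  b <- -(crossprod(LUx, dx) + crossprod(LUy, dy))
  t_hat <- tryCatch(solve(A, b), error = function(e) {
    solve(A + diag(1e-12 * max(diag(A)), mm), b)   # near-singular guard
  })
  y[idx, 1L] <- y[idx, 1L] + t_hat * tang[, 1L]
  y[idx, 2L] <- y[idx, 2L] + t_hat * tang[, 2L]
  y
}

#' Slide semi-landmarks of an aligned sample by bending energy
#'
#' Each semi-landmark may move only along its local tangent direction (the
#' chord between its two slider-scheme neighbours in the current shape); the
#' vector of slide magnitudes minimizes the thin-plate-spline bending energy of
#' the displaced shape relative to the model reference, solved exactly as a
#' linear system. Fixed landmarks never move. Shapes are re-centered and
#' re-scaled to unit centroid size afterwards.
#'
#' @param fit a `gpa_fit` (or a `p x 2 x n` array of aligned shapes).
#' @param model a [bending_energy_model()] built on the reference (usually the
#'   Procrustes consensus).
#' @param scheme a [slider_scheme]; defaults to `fit$scheme`.
#' @param renormalize re-center and re-scale each shape after sliding (the
#'   pipeline default); set `FALSE` to inspect the raw minimizer, for which
#'   bending energy is guaranteed not to increase.
#' @return The input with slid coordinates (`gpa_fit` in, `gpa_fit` out, with
#'   `slid = TRUE` and refreshed `shapes` and `consensus`).
#' @export
slide_semilandmarks <- function(fit, model, scheme = NULL, renormalize = TRUE) {
  is_fit <- inherits(fit, "gpa_fit")
  coords <- if (is_fit) fit$coords else fit
  if (is.null(scheme) && is_fit) scheme <- fit$scheme
  if (is.null(scheme)) stop("a slider scheme is required")
  if (nrow(model$reference) != dim(coords)[1L])
    stop("model and sample disagree on the number of points")
  for (i in seq_len(dim(coords)[3L])) {
    y <- slide_one(coords[, , i], model$reference, model$Lk, scheme)
    coords[, , i] <- if (renormalize) center_scale(y) else y
  }
  if (!is_fit) return(coords)
  fit$coords <- coords
  fit$consensus <- apply(coords, c(1L, 2L), mean)
  fit$shapes <- t(apply(coords, 3L, function(m) as.vector(t(m))))
  colnames(fit$shapes) <- paste0(rep(c("x", "y"), nrow(model$reference)),
                                 rep(seq_len(nrow(model$reference)), each = 2L))
  fit$slid <- TRUE
  fit
}
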