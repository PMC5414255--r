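#' Permutation shape ANOVA (residual randomization)
#'
#' Multivariate linear-model ANOVA on shape coordinates with sequential
#' (type-I) sums of squares and significance assessed by residual
#' randomization: for each model term, the residuals of its reduced model are
#' permuted across specimens, added back to the reduced-model fitted values,
#' and the term's F statistic recomputed. The reported effect size
#' `Z = (F_obs - mean F_perm) / sd F_perm` locates the observed statistic in
#' its permutation distribution (which includes the observed value), and
#' `Pr(>F)` is the proportion of the distribution at or above the observed F.
#'
#' This is the standard randomization scheme for high-dimensional Procrustes
#' data, where classical parametric MANOVA breaks down because the number of
#' shape variables exceeds the sample size.
#'
#' @param formula model formula whose left-hand side is an `n x k` numeric
#'   matrix (e.g. `shapes ~ tooth * taxon`); terms are tested sequentially in
#'   formula order.
#' @param data optional list/data frame/environment in which to evaluate the
#'   formula.
#' @param n_perm number of random permutations (>= 99 recommended).
#' @param seed integer seed for the permutations.
#' @return Object of class `shape_anova`: `table` (data frame with Df, SS, MS,
#'   Rsq, F, Z, `Pr(>F)` rows per term plus Residuals and Total), `n_perm`,
#'   `seed`, `term_labels`.
#' @export
shape_anova <- function(formula, data = NULL, n_perm = 999L, seed = NULL) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  Y <- as.matrix(stats::model.response(mf))
  n <- nrow(Y)
  trm <- stats::terms(formula, data = data)
  labels <- attr(trm, "term.labels")
  if (!length(labels)) stop("the model needs at least one term")

  for (v in names(mf)[-1L]) {
    if (is.character(mf[[v]])) mf[[v]] <- factor(mf[[v]])
    if (is.factor(mf[[v]]) && nlevels(droplevels(mf[[v]])) < 2L)
      stop("factor '", v, "' has a single level")
  }
  fac <- names(mf)[-1L][vapply(mf[-1L], is.factor, TRUE)]
  if (length(fac) == 2L) {
    tab <- table(mf[[fac[1L]]], mf[[fac[2L]]])
    if (any(tab == 0L))
      warning("empty cells in the ", fac[1L], " x ", fac[2L],
              " design; sequential SS still computed")
  }

  ## cumulative design matrices: intercept, then one term at a time
  designs <- vector("list", length(labels) + 1L)
  designs[[1L]] <- matrix(1, n, 1L)
  for (j in seq_along(labels)) {
    f_j <- stats::reformulate(labels[seq_len(j)])
    designs[[j + 1L]] <- stats::model.matrix(f_j, data = mf)
  }
  qrs <- lapply(designs, qr)
  ranks <- vapply(qrs, `[[`, 0L, "rank")
  df_terms <- diff(ranks)
  if (any(df_terms == 0L)) stop("aliased model term (zero df): ",
                                paste(labels[df_terms == 0L], collapse = ", "))
  df_res <- n - ranks[length(ranks)]
  if (df_res <= 0L) stop("no residual degrees of freedom")

  rss <- function(qr_obj, y) sum(qr.resid(qr_obj, y)^2)
  ss_total <- sum(sweep(Y, 2L, colMeans(Y))^2)
  rss_obs <- vapply(qrs, rss, 0, y = Y)
  ss_obs <- -diff(rss_obs)
  ms_res_obs <- rss_obs[length(rss_obs)] / df_res
  f_obs <- (ss_obs / df_terms) / ms_res_obs

  nt <- length(labels)
  f_perm <- matrix(NA_real_, n_perm, nt)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      perm <- sample.int(n)
      for (j in seq_len(nt)) {
        fit_red <- qr.fitted(qrs[[j]], Y)
        res_red <- Y - fit_red
        Yp <- fit_red + res_red[perm, , drop = FALSE]
        rss_red <- rss(qrs[[j]], Yp)
        rss_ful <- rss(qrs[[j + 1L]], Yp)
        ms_res_p <- rss(qrs[[nt + 1L]], Yp) / df_res
        f_perm[b, j] <- ((rss_red - rss_ful) / df_terms[j]) / ms_res_p
      }
    }
  })

  p_val <- z_val <- numeric(nt)
  for (j in seq_len(nt)) {
    dist <- c(f_obs[j], f_perm[, j])
    p_val[j] <- mean(dist >= f_obs[j])
    z_val[j] <- (f_obs[j] - mean(dist)) / stats::sd(dist)
  }

  tab <- data.frame(
    Df = c(df_terms, df_res, n - 1L),
    SS = c(ss_obs, rss_obs[length(rss_obs)], ss_total),
    MS = c(ss_obs / df_terms, ms_res_obs, NA),
    Rsq = c(ss_obs / ss_total, rss_obs[length(rss_obs)] / ss_total, 1),
    F = c(f_obs, NA, NA),
    Z = c(z_val, NA, NA),
    `Pr(>F)` = c(p_val, NA, NA),
    row.names = c(labels, "Residuals", "Total"),
    check.names = FALSE)

  structure(list(table = tab, n_perm = n_perm, seed = seed,
                 term_labels = labels),
            class = "shape_anova")
}

#' @export
print.shape_anova <- function(x, digits = 5, ...) {
  cat("Permutation shape ANOVA (sequential SS, residual randomization,",
      x$n_perm, "permutations)\n\n")
  tab <- x$table
  tab$`Pr(>F)` <- ifelse(is.na(tab$`Pr(>F)`), NA,
                         format.pval(tab$`Pr(>F)`, digits = 3))
  print(format(tab, digits = digits), quote = FALSE)
  invisible(x)
}

#' Classical MANOVA with Pillai's trace
#'
#' Thin wrapper over [stats::manova()] on retained PC scores: reports Pillai's
#' trace with the standard approximate F and its degrees of freedom. Used for
#' the per-tooth taxon comparisons, where the score space is low-dimensional
#' enough for parametric MANOVA.
#'
#' @param scores `n x m` numeric score matrix with `m < n - nlevels(groups)`.
#' @param groups grouping factor.
#' @return Object of class `manova_pillai`: `pillai`, `approx_f`, `num_df`,
#'   `den_df`, `p`.
#' @export
manova_pillai <- function(scores, groups) {
  scores <- as.matrix(scores)
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (ncol(scores) >= nrow(scores) - nlevels(groups) + 1L)
    stop("within-group covariance singular: retain fewer PCs (m must be < n - groups)")
  fit <- stats::manova(scores ~ groups)
  st <- summary(fit, test = "Pillai")$stats
  structure(list(pillai = unname(st["groups", "Pillai"]),
                 approx_f = unname(st["groups", "approx F"]),
                 num_df = unname(st["groups", "num Df"]),
                 den_df = unname(st["groups", "den Df"]),
                 p = unname(st["groups", "Pr(>F)"])),
            class = "manova_pillai")
}

#' @export
print.manova_pillai <- function(x, ...) {
  cat(sprintf("MANOVA (Pillai): %.4f, approx F = %.4f on (%d, %d) df, p = %s\n",
              x$pillai, x$approx_f, x$num_df, x$den_df,
              format.pval(x$p, digits = 3)))
  invisible(x)
}
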