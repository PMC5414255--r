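#' Semi-landmark slider scheme
#'
#' Defines how a digitized tooth outline is discretized: a fixed number of
#' anatomical landmarks (anchor points at enamel-fold extrema) joined by curves,
#' each curve resampled into a given number of equidistant semi-landmarks.
#' Semi-landmarks are allowed to slide along their curve during Procrustes
#' superimposition; the scheme records, for every semi-landmark, its two
#' immediate neighbours along the curve chain (fixed landmarks act as anchors at
#' the curve ends) so that local tangents can be estimated.
#'
#' The default mirrors the dental digitization protocol used throughout this
#' package: 8 landmarks, 8 curves carrying (22, 22, 22, 22, 22, 22, 23, 23)
#' semi-landmarks, i.e. 178 semi-landmarks and 186 points in total. Curve `c`
#' runs from landmark `c` to landmark `c %% n_landmarks + 1`, closing the
#' outline.
#'
#' @param counts_per_curve positive integer vector, one entry per curve: the
#'   number of semi-landmarks sampled on that curve (flanking landmarks
#'   excluded).
#' @param n_landmarks number of fixed landmarks; must equal the number of
#'   curves for a closed outline.
#' @return An object of class `slider_scheme`: a list with `n_landmarks`,
#'   `counts_per_curve`, `n_semilandmarks`, `p` (total points),
#'   `semilandmark_index` (flat indices of all semi-landmarks),
#'   `curve_of_point` (curve id per semi-landmark) and `sliders`, an
#'   `n_semilandmarks x 3` matrix of (before, slider, after) flat indices.
#'   Flat point order is landmarks first, then curves in order.
#' @examples
#' sch <- slider_scheme()
#' sch$p                      # 186
#' head(sch$sliders)
#' @export
slider_scheme <- function(counts_per_curve = c(22L, 22L, 22L, 22L, 22L, 22L, 23L, 23L),
                          n_landmarks = 8L) {
  counts_per_curve <- as.integer(counts_per_curve)
  n_landmarks <- as.integer(n_landmarks)
  if (length(counts_per_curve) != n_landmarks)
    stop("need exactly one semi-landmark count per curve (one curve per landmark)")
  if (any(counts_per_curve < 1L))
    stop("every curve must carry at least one semi-landmark")

  n_semi <- sum(counts_per_curve)
  p <- n_landmarks + n_semi

  sliders <- matrix(0L, n_semi, 3L,
                    dimnames = list(NULL, c("before", "slider", "after")))
  curve_of_point <- integer(n_semi)
  offset <- n_landmarks
  row <- 1L
  for (cv in seq_len(n_landmarks)) {
    k <- counts_per_curve[cv]
    lm_start <- cv
    lm_end <- cv %% n_landmarks + 1L
    chain <- c(lm_start, offset + seq_len(k), lm_end)
    for (j in seq_len(k)) {
      sliders[row, ] <- chain[c(j, j + 1L, j + 2L)]
      curve_of_point[row] <- cv
      row <- row + 1L
    }
    offset <- offset + k
  }

  structure(
    list(n_landmarks = n_landmarks,
         counts_per_curve = counts_per_curve,
         n_semilandmarks = n_semi,
         p = p,
         semilandmark_index = n_landmarks + seq_len(n_semi),
         curve_of_point = curve_of_point,
         sliders = sliders),
    class = "slider_scheme")
}

#' @export
print.slider_scheme <- function(x, ...) {
  cat("Slider scheme:", x$n_landmarks, "landmarks,",
      x$n_semilandmarks, "semi-landmarks on", length(x$counts_per_curve),
      "curves (", paste(x$counts_per_curve, collapse = ","), ") =>",
      x$p, "points\n")
  invisible(x)
}
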