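#' Default taxon sampling layout
#'
#' The default multi-taxon study design emulated by the synthetic generator:
#' 15 taxon codes (two caballine horses, African and Asian asses, zebras, and
#' an ass/horse hybrid group) with per-taxon sample sizes for each of the four
#' mandibular cheek teeth P3, P4, M1, M2. Group sizes are deliberately
#' unbalanced, down to groups of 2, so that small-sample edge cases are
#' exercised by default.
#'
#' @return data frame with columns `taxon`, `P3`, `P4`, `M1`, `M2`.
#' @export
default_taxon_table <- function() {
  data.frame(
    taxon = c("CBL", "PRZ", "AFR", "ASN", "KNG", "MNG", "ONG", "KHR",
              "KLN", "HMP", "GRV", "ZBR", "QGA", "BRC", "HBR"),
    P3 = c(15, 9, 7, 11, 12, 13, 7, 7, 9, 2, 3, 4, 3, 8, 4),
    P4 = c(15, 8, 7, 11, 13, 10, 8, 8, 12, 3, 3, 4, 3, 8, 4),
    M1 = c(15, 8, 7, 10, 13, 13, 7, 8, 10, 2, 3, 4, 3, 8, 4),
    M2 = c(15, 8, 7, 10, 13, 13, 7, 6, 11, 3, 3, 5, 3, 8, 4),
    stringsAsFactors = FALSE)
}

#' Default species phylogeny of the synthetic study
#'
#' A rooted 10-taxon tree with the caballine / (asses+hemiones, zebras) clade
#' structure of extant equids and arbitrary unit-scale branch lengths. Used as
#' the default evolutionary scaffold for Brownian-motion taxon effects.
#'
#' @return a `phylo` object.
#' @export
default_equid_tree <- function() {
  read_tree(text = paste0(
    "((CBL:0.5,PRZ:0.5):2.5,",
    "(((AFR:0.6,ASN:0.6):0.9,(KNG:0.7,ONG:0.7):0.8):0.7,",
    "((QGA:0.5,BRC:0.5):0.9,(GRV:1.0,ZBR:1.0):0.4):0.8):1.0);"))
}

## outline of the template tooth at angle theta: an ellipse (aspect ratio
## `aspect`) with 8 sinusoidal inward enamel folds of relative depth
## `fold_amp`; fold extrema (landmark anchors) sit at theta = 2*pi*k/8.
## `deviation(theta)` multiplies the radius (smooth displacement fields).
outline_points <- function(theta, fold_amp, aspect, deviation = NULL) {
  r <- 1 + fold_amp * cos(8 * theta) / 2
  if (!is.null(deviation)) r <- r * (1 + deviation)
  cbind(aspect * r * cos(theta), r * sin(theta))
}

## 5 smooth low-frequency radial basis fields, evaluated at theta
field_basis <- function(theta) {
  cbind(cos(2 * theta), sin(2 * theta), cos(3 * theta),
        sin(3 * theta), cos(4 * theta))
}

landmark_thetas <- function(n_landmarks) 2 * pi * (seq_len(n_landmarks) - 1) / n_landmarks

## build one synthetic specimen: template outline deformed by smooth fields
## with coefficients `coefs` (length 5), plus iid landmark/curve noise, then a
## random similarity transform (and mirroring for right-sided specimens)
build_specimen <- function(id, coefs, scheme, fold_amp, aspect, n_dense,
                           noise_sd, jitter, side, taxon = NA, tooth = NA,
                           base_size = 100) {
  nl <- scheme$n_landmarks
  th_lm <- landmark_thetas(nl)
  dev_at <- function(th) as.vector(field_basis(th) %*% coefs)

  lms <- outline_points(th_lm, fold_amp, aspect, dev_at(th_lm))
  lms <- lms + matrix(stats::rnorm(length(lms), 0, noise_sd), ncol = 2L)
  curves <- vector("list", nl)
  for (cv in seq_len(nl)) {
    th <- seq(th_lm[cv], th_lm[cv] + 2 * pi / nl, length.out = n_dense)
    pts <- outline_points(th, fold_amp, aspect, dev_at(th))
    pts <- pts + matrix(stats::rnorm(length(pts), 0, noise_sd + jitter), ncol = 2L)
    pts[1L, ] <- lms[cv, ]                      # curve anchored at its landmarks
    pts[n_dense, ] <- lms[cv %% nl + 1L, ]
    curves[[cv]] <- pts
  }

  ## random similarity transform: digitized images differ in position,
  ## orientation and magnification
  ang <- stats::runif(1, -pi, pi)
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L)
  sc <- base_size * exp(stats::rnorm(1, 0, 0.15))
  shift <- stats::runif(2, 200, 800)
  tf <- function(m) sweep(m %*% R * sc, 2L, shift, `+`)
  lms <- tf(lms); curves <- lapply(curves, tf)

  sp <- tooth_specimen(id = id, landmarks = lms, curves = curves,
                       taxon = taxon, tooth = tooth, side = "left")
  if (side == "right") {                        # store as right-digitized
    sp$side <- "right"
    cx <- mean(range(c(sp$landmarks[, 1L], unlist(lapply(sp$curves, `[`, , 1L)))))
    flip <- function(m) { m[, 1L] <- 2 * cx - m[, 1L]; m }
    sp$landmarks <- flip(sp$landmarks)
    sp$curves <- lapply(sp$curves, flip)
  }
  sp
}

#' Synthetic template tooth
#'
#' The noiseless parametric tooth outline used by the synthetic-study
#' generator: a smoothed ellipse with 8 sinusoidal inward folds mimicking
#' enamel flexid lobes, with 8 anchor landmarks at the fold extrema and 8
#' dense digitized curves between them. Purely synthetic stand-in geometry —
#' it reproduces the *structure* of a digitized tooth, not real anatomy.
#'
#' @param scheme a [slider_scheme].
#' @param fold_amp relative fold depth (0 = plain ellipse; must be < 2 for a
#'   non-self-intersecting outline).
#' @param aspect major/minor axis ratio of the base ellipse.
#' @param n_dense digitized points per curve.
#' @return a [tooth_specimen] with zero noise at canonical position/scale.
#' @export
make_template <- function(scheme = slider_scheme(), fold_amp = 0.25,
                          aspect = 1.7, n_dense = 60L) {
  if (fold_amp < 0 || fold_amp >= 2) stop("fold_amp must be in [0, 2) for a valid outline")
  nl <- scheme$n_landmarks
  th_lm <- landmark_thetas(nl)
  lms <- outline_points(th_lm, fold_amp, aspect)
  curves <- lapply(seq_len(nl), function(cv) {
    th <- seq(th_lm[cv], th_lm[cv] + 2 * pi / nl, length.out = n_dense)
    outline_points(th, fold_amp, aspect)
  })
  tooth_specimen(id = "template", landmarks = lms, curves = curves)
}

#' Simulate species means under Brownian motion
#'
#' Draws tip deviations from a zero-mean Gaussian with covariance
#' `rate * C` per trait dimension, where `C` is the tree's Brownian-motion
#' covariance, and adds them to a template trait vector.
#'
#' @param tree `phylo` object with branch lengths.
#' @param template numeric vector (length d) of ancestral/template trait
#'   values, or a single number recycled.
#' @param rate Brownian rate (variance per unit branch length); `rate = 0`
#'   returns the template at every tip.
#' @param d number of trait dimensions when `template` is length 1.
#' @param seed optional integer seed.
#' @return `N x d` matrix of tip values, rownames = tip labels.
#' @export
simulate_bm_means <- function(tree, template = 0, rate = 1, d = NULL, seed = NULL) {
  if (is.null(d)) d <- length(template)
  template <- rep_len(template, d)
  C <- phylo_covariance(tree)
  N <- nrow(C)
  with_seed(seed, {
    dev <- if (rate == 0) matrix(0, N, d) else
      t(chol(C)) %*% matrix(stats::rnorm(N * d, 0, sqrt(rate)), N, d)
    out <- sweep(dev, 2L, template, `+`)
    rownames(out) <- rownames(C)
    out
  })
}

#' Generate a complete synthetic dental study
#'
#' Produces a seeded fake study with the statistical structure the analysis
#' pipeline assumes: per-taxon/per-tooth samples of digitized tooth outlines
#' whose shapes are the template plus (i) a taxon effect — Brownian-motion
#' divergence along a phylogeny for taxa on the tree, independent draws for
#' the rest — (ii) a tooth-position effect, (iii) a taxon-by-tooth
#' interaction, and (iv) within-group digitization noise. Effects are smooth
#' low-frequency radial displacement fields (5 harmonic basis functions of
#' outline angle), not independent per-landmark offsets, so group differences
#' look anatomically coherent. Roughly half of the specimens are flagged
#' `side = "right"` and stored mirrored, to exercise [mirror_to_left()]. Each
#' specimen additionally receives a random position/rotation/scale, removed
#' later by Procrustes superimposition.
#'
#' Identical `seed` and parameters give byte-identical output.
#'
#' @param seed integer; fully determines the study.
#' @param taxa_table data frame as [default_taxon_table()] (columns `taxon`
#'   then one count column per tooth).
#' @param scheme a [slider_scheme].
#' @param tree phylogeny over a subset of the taxa ([default_equid_tree()]).
#' @param taxon_effect_scale,tooth_effect_scale,interaction_scale standard
#'   deviations of the basis-field coefficients of the three effects
#'   (dimensionless, relative radius units).
#' @param bm_rate Brownian rate for tree-taxon effects, per unit branch
#'   length; default `taxon_effect_scale^2 / mean(diag(C))` so that tree and
#'   non-tree taxa diverge comparably.
#' @param noise_sd within-group isotropic coordinate noise (template units,
#'   outline radius ~ 1).
#' @param digitization_jitter extra coordinate noise on curve points only.
#' @param fold_amp,aspect,n_dense template geometry, see [make_template()].
#' @param right_fraction expected fraction of right-sided specimens.
#' @param dir if non-NULL, write `study.tps`, `metadata.csv` and `tree.nwk`
#'   into this directory and return the paths invisibly.
#' @return (when `dir` is NULL) list of class `synthetic_study`:
#'   `specimens` (list of [tooth_specimen]), `metadata` (data frame),
#'   `tree`, `taxon_coefs`, `tooth_coefs`, `params`.
#' @export
simulate_tooth_study <- function(seed,
                                 taxa_table = default_taxon_table(),
                                 scheme = slider_scheme(),
                                 tree = default_equid_tree(),
                                 taxon_effect_scale = 0.05,
                                 tooth_effect_scale = 0.04,
                                 interaction_scale = 0.02,
                                 bm_rate = NULL,
                                 noise_sd = 0.01,
                                 digitization_jitter = 0.002,
                                 fold_amp = 0.25, aspect = 1.7, n_dense = 60L,
                                 right_fraction = 0.5,
                                 dir = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  teeth <- setdiff(names(taxa_table), "taxon")
  taxa <- taxa_table$taxon
  nb <- 5L                                   # basis fields

  study <- with_seed(as.integer(seed), {
    on_tree <- intersect(taxa, tree$tip.label)
    if (is.null(bm_rate)) {
      C <- phylo_covariance(tree)
      bm_rate <- taxon_effect_scale^2 / mean(diag(C))
    }
    taxon_coefs <- matrix(0, length(taxa), nb, dimnames = list(taxa, NULL))
    if (length(on_tree) >= 3L) {
      bm <- simulate_bm_means(ape::keep.tip(tree, on_tree), template = 0,
                              rate = bm_rate, d = nb)
      taxon_coefs[rownames(bm), ] <- bm
    }
    off_tree <- setdiff(taxa, on_tree)
    if (length(off_tree))
      taxon_coefs[off_tree, ] <- stats::rnorm(length(off_tree) * nb, 0, taxon_effect_scale)

    tooth_coefs <- matrix(stats::rnorm(length(teeth) * nb, 0, tooth_effect_scale),
                          length(teeth), nb, dimnames = list(teeth, NULL))
    inter_coefs <- array(stats::rnorm(length(taxa) * length(teeth) * nb, 0,
                                      interaction_scale),
                         c(length(taxa), length(teeth), nb),
                         dimnames = list(taxa, teeth, NULL))

    specimens <- list()
    meta <- list()
    for (ti in seq_along(taxa)) for (to in seq_along(teeth)) {
      n_g <- taxa_table[[teeth[to]]][ti]
      for (k in seq_len(n_g)) {
        id <- sprintf("%s_%s_%02d", taxa[ti], teeth[to], k)
        side <- if (stats::runif(1) < right_fraction) "right" else "left"
        coefs <- taxon_coefs[ti, ] + tooth_coefs[to, ] + inter_coefs[ti, to, ]
        specimens[[id]] <- build_specimen(
          id, coefs, scheme, fold_amp, aspect, n_dense,
          noise_sd, digitization_jitter, side,
          taxon = taxa[ti], tooth = teeth[to])
        meta[[id]] <- data.frame(specimen_id = id, taxon = taxa[ti],
                                 tooth = teeth[to], side = side,
                                 stringsAsFactors = FALSE)
      }
    }
    list(specimens = unname(specimens),
         metadata = do.call(rbind, c(meta, list(make.row.names = FALSE))),
         taxon_coefs = taxon_coefs, tooth_coefs = tooth_coefs)
  })

  study$tree <- tree
  study$params <- list(seed = seed, taxon_effect_scale = taxon_effect_scale,
                       tooth_effect_scale = tooth_effect_scale,
                       interaction_scale = interaction_scale,
                       bm_rate = bm_rate, noise_sd = noise_sd,
                       digitization_jitter = digitization_jitter,
                       fold_amp = fold_amp, aspect = aspect,
                       n_dense = n_dense, right_fraction = right_fraction)
  class(study) <- "synthetic_study"

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    tps <- file.path(dir, "study.tps")
    md <- file.path(dir, "metadata.csv")
    nwk <- file.path(dir, "tree.nwk")
    write_tps(study$specimens, tps)
    utils::write.csv(study$metadata, md, row.names = FALSE, quote = FALSE)
    ape::write.tree(study$tree, nwk)
    return(invisible(list(tps = tps, metadata = md, tree = nwk)))
  }
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic dental study:", length(x$specimens), "specimens,",
      length(unique(x$metadata$taxon)), "taxa x",
      length(unique(x$metadata$tooth)), "tooth positions (seed",
      x$params$seed, ")\n")
  invisible(x)
}

#' Tiny fixture study for unit tests and examples
#'
#' Three well-separated taxa, one tooth position, four specimens each — small
#' enough for fast end-to-end runs.
#'
#' @param seed integer seed.
#' @param scheme slider scheme (default a light 34-point scheme).
#' @param dir optional output directory, as in [simulate_tooth_study()].
#' @return see [simulate_tooth_study()].
#' @export
fixture_study <- function(seed = 1L,
                          scheme = slider_scheme(c(3L, 3L, 3L, 3L, 3L, 3L, 4L, 4L)),
                          dir = NULL) {
  tab <- data.frame(taxon = c("AAA", "BBB", "CCC"), M1 = c(4L, 4L, 4L),
                    stringsAsFactors = FALSE)
  simulate_tooth_study(seed, taxa_table = tab, scheme = scheme,
                       tree = fixture_tree(), taxon_effect_scale = 0.08,
                       tooth_effect_scale = 0, interaction_scale = 0,
                       n_dense = 40L, dir = dir)
}

## 3-tip helper tree over the fixture taxa so BM plumbing stays exercised
fixture_tree <- function() read_tree(text = "((AAA:1,BBB:1):1,CCC:2);")
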