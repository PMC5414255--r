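#' Align a dental study
#'
#' End-to-end shape capture: mirrors right-sided specimens to the left,
#' resamples every curve into the scheme's equidistant semi-landmarks, and
#' runs generalized Procrustes superimposition with bending-energy sliding —
#' once per tooth position (the superimposition used for taxonomic analyses)
#' and once jointly across all teeth (required when shapes are compared
#' *across* tooth positions, as in the factorial ANOVA and the anatomical
#' discriminant model).
#'
#' @param specimens list of [tooth_specimen] with `taxon`/`tooth`/`side`
#'   metadata (see [attach_metadata()]), or a `synthetic_study`.
#' @param scheme a [slider_scheme].
#' @param slide slide semi-landmarks by bending energy.
#' @param slide_cycles GPA+slide cycles, see [gpa()].
#' @param skip_resample passed to [resample_curves()].
#' @return Object of class `aligned_study`: `joint` (a [gpa()] fit of all
#'   specimens), `per_tooth` (named list of per-tooth fits), `meta` (data
#'   frame id/taxon/tooth/side, row order matching `joint`), `configs`
#'   (resampled raw configurations), `scheme`.
#' @export
align_study <- function(specimens, scheme = slider_scheme(), slide = TRUE,
                        slide_cycles = 5L, skip_resample = FALSE) {
  if (inherits(specimens, "synthetic_study")) specimens <- specimens$specimens
  n_in <- length(specimens)
  specimens <- lapply(specimens, function(sp)
    if (sp$side == "right") mirror_to_left(sp) else sp)
  configs <- lapply(specimens, resample_curves, scheme = scheme,
                    skip_resample = skip_resample)
  meta <- data.frame(
    id = vapply(specimens, `[[`, "", "id"),
    taxon = vapply(specimens, function(s) as.character(s$taxon), ""),
    tooth = vapply(specimens, function(s) as.character(s$tooth), ""),
    side = vapply(specimens, `[[`, "", "side"),
    stringsAsFactors = FALSE)
  stopifnot(nrow(meta) == n_in)   # never silently drop specimens

  joint <- gpa(configs, scheme = scheme, slide = slide,
               slide_cycles = slide_cycles)
  rownames(joint$shapes) <- meta$id

  per_tooth <- list()
  for (to in unique(meta$tooth)) {
    ix <- which(meta$tooth == to)
    if (length(ix) >= 2L) {
      per_tooth[[to]] <- gpa(configs[ix], scheme = scheme, slide = slide,
                             slide_cycles = slide_cycles)
      rownames(per_tooth[[to]]$shapes) <- meta$id[ix]
      attr(per_tooth[[to]], "rows") <- ix
    }
  }

  structure(list(joint = joint, per_tooth = per_tooth, meta = meta,
                 configs = configs, scheme = scheme),
            class = "aligned_study")
}

#' @export
print.aligned_study <- function(x, ...) {
  cat("Aligned study:", nrow(x$meta), "specimens,",
      length(unique(x$meta$taxon)), "taxa,",
      length(x$per_tooth), "tooth positions;",
      if (x$joint$slid) "slid semi-landmarks" else "no sliding", "\n")
  invisible(x)
}

#' Aligned coordinates as a flat table
#'
#' One row per specimen: id, taxon, tooth, centroid size, then the Procrustes
#' coordinates x1,y1,...,xp,yp of the joint superimposition (the layout of a
#' shareable morphometric dataset).
#'
#' @param aligned an [align_study()] result.
#' @return data frame.
#' @export
coords_table <- function(aligned) {
  data.frame(specimen_id = aligned$meta$id, taxon = aligned$meta$taxon,
             tooth = aligned$meta$tooth,
             centroid_size = aligned$joint$centroid_sizes,
             aligned$joint$shapes, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Factorial shape ANOVA of a study
#'
#' Sequential permutation ANOVA of the jointly superimposed shapes on
#' anatomical position, taxon and their interaction (in that order):
#' `shapes ~ tooth * taxon`. A significant interaction means taxonomic
#' differences vary across the tooth row, motivating per-tooth discriminant
#' analyses.
#'
#' @param aligned an [align_study()] result.
#' @param n_perm,seed see [shape_anova()].
#' @return a [shape_anova()] object.
#' @export
study_anova <- function(aligned, n_perm = 999L, seed = NULL) {
  dat <- list(shapes = aligned$joint$shapes,
              tooth = factor(aligned$meta$tooth),
              taxon = factor(aligned$meta$taxon))
  f <- if (nlevels(dat$tooth) > 1L) shapes ~ tooth * taxon else shapes ~ taxon
  shape_anova(f, data = dat, n_perm = n_perm, seed = seed)
}

#' Anatomical discriminant model (tooth position)
#'
#' CVA + twofold cross-validated classification of the jointly superimposed
#' shapes into the tooth-position classes, after PCA reduction.
#'
#' @param aligned an [align_study()] result.
#' @param threshold PCA variance retention.
#' @param rounds,seed see [crossval_classify()].
#' @return list of class `anatomy_report`: `pca`, `cva`, `report`.
#' @export
anatomy_classification <- function(aligned, threshold = 0.99,
                                   rounds = 10000L, seed = NULL) {
  pca <- shape_pca(aligned$joint$shapes, threshold = threshold)
  sc <- retained_scores(pca)
  rownames(sc) <- aligned$meta$id
  groups <- factor(aligned$meta$tooth)
  fit <- cva(sc, groups)
  rep <- crossval_classify(sc, groups, rounds = rounds, seed = seed)
  structure(list(pca = pca, cva = fit, report = rep), class = "anatomy_report")
}

#' @export
print.anatomy_report <- function(x, ...) {
  cat("Anatomical (tooth position) discriminant model\n")
  print(x$report)
  invisible(x)
}

#' Per-tooth taxonomic discriminant models
#'
#' For each tooth position separately (its own superimposition): PCA at the
#' variance threshold, MANOVA (Pillai) of the taxa on the retained scores
#' when feasible, CVA, and twofold cross-validated classification.
#'
#' @param aligned an [align_study()] result.
#' @param threshold PCA variance retention.
#' @param rounds,seed see [crossval_classify()].
#' @return named list (one entry per tooth) of lists with `pca`, `manova`
#'   (or NULL if the score space is too large for parametric MANOVA), `cva`,
#'   `report`; class `taxon_report`.
#' @export
taxon_classification <- function(aligned, threshold = 0.99,
                                 rounds = 10000L, seed = NULL) {
  out <- list()
  for (to in names(aligned$per_tooth)) {
    fit_g <- aligned$per_tooth[[to]]
    rows <- attr(fit_g, "rows")
    groups <- factor(aligned$meta$taxon[rows])
    pca <- shape_pca(fit_g$shapes, threshold = threshold)
    sc <- retained_scores(pca)
    rownames(sc) <- aligned$meta$id[rows]
    man <- tryCatch(manova_pillai(sc, groups), error = function(e) NULL)
    fit <- cva(sc, groups)
    rep <- crossval_classify(sc, groups, rounds = rounds, seed = seed)
    out[[to]] <- list(pca = pca, manova = man, cva = fit, report = rep)
  }
  structure(out, class = "taxon_report")
}

#' @export
print.taxon_report <- function(x, ...) {
  for (to in names(x)) {
    cat("==", to, "==\n")
    if (!is.null(x[[to]]$manova)) print(x[[to]]$manova)
    print(x[[to]]$report)
  }
  invisible(x)
}

#' Phylogenetic signal of each tooth's shape
#'
#' For every tooth position: re-superimposes the specimens of the taxa present
#' on the tree (their own GPA), computes species mean shapes, estimates the
#' multivariate K statistic with a permutation test, and builds the
#' phylomorphospace (PCA of the species means + squared-change-parsimony
#' internal nodes).
#'
#' @param aligned an [align_study()] result.
#' @param tree a `phylo` object whose tip labels are taxon codes.
#' @param n_perm,seed see [kmult()].
#' @param threshold PCA variance retention for the phylomorphospace.
#' @param slide slide semi-landmarks in the species-subset GPA.
#' @return named list per tooth with `means`, `kmult`, `phylomorphospace`;
#'   class `physignal_report`.
#' @export
study_physignal <- function(aligned, tree, n_perm = 1000L, seed = NULL,
                            threshold = 0.99, slide = TRUE) {
  out <- list()
  for (to in names(aligned$per_tooth)) {
    rows <- which(aligned$meta$tooth == to &
                    aligned$meta$taxon %in% tree$tip.label)
    taxa <- aligned$meta$taxon[rows]
    if (length(unique(taxa)) < 3L) next
    fit <- gpa(aligned$configs[rows], scheme = aligned$scheme, slide = slide)
    means <- rowsum(fit$shapes, taxa) / as.vector(table(taxa))
    km <- kmult(means, tree, n_perm = n_perm, seed = seed)
    pms <- phylomorphospace(means, tree, threshold = threshold)
    out[[to]] <- list(means = means, kmult = km, phylomorphospace = pms)
  }
  structure(out, class = "physignal_report")
}

#' @export
print.physignal_report <- function(x, ...) {
  cat("Phylogenetic signal per tooth:\n")
  for (to in names(x))
    cat(sprintf("  %-4s K = %.4f  p = %.4g\n", to, x[[to]]$kmult$K,
                x[[to]]$kmult$p))
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage on one dataset: alignment (per tooth and joint),
#' factorial shape ANOVA, anatomical and taxonomic discriminant models with
#' cross-validated classification, and the phylogenetic-signal layer. All
#' stochastic stages take the single `seed`; defaults follow standard
#' practice for this kind of study (99% PC retention, 10 000 CV rounds,
#' 999/1000 permutations) — scale `rounds`/`n_perm` down for quick runs.
#'
#' @param specimens list of [tooth_specimen] (or a `synthetic_study`);
#'   alternatively give `tps`/`metadata` file paths.
#' @param tree `phylo` object or newick path; NULL skips the phylogenetic
#'   layer.
#' @param tps,metadata optional file paths read with [read_tps()] and
#'   [read_study_metadata()] when `specimens` is NULL.
#' @param scheme a [slider_scheme].
#' @param threshold PCA variance retention.
#' @param rounds cross-validation rounds.
#' @param n_perm_anova,n_perm_k permutation counts.
#' @param seed integer seed recorded in the report and used by every
#'   stochastic stage.
#' @param slide slide semi-landmarks.
#' @return Object of class `tooth_study_report` with elements `aligned`,
#'   `anova`, `anatomy`, `taxa`, `physignal`, `params`, `timing`.
#' @export
analyze_tooth_study <- function(specimens = NULL, tree = NULL,
                                tps = NULL, metadata = NULL,
                                scheme = slider_scheme(), threshold = 0.99,
                                rounds = 10000L, n_perm_anova = 999L,
                                n_perm_k = 1000L, seed = 1L, slide = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  if (is.null(specimens)) {
    if (is.null(tps) || is.null(metadata))
      stop("give either specimens or tps + metadata paths")
    specimens <- read_tps(tps, metadata = read_study_metadata(metadata))
  }
  if (is.character(tree)) tree <- read_tree(tree)

  aligned <- align_study(specimens, scheme = scheme, slide = slide)
  anova <- study_anova(aligned, n_perm = n_perm_anova, seed = seed)
  anatomy <- if (length(unique(aligned$meta$tooth)) >= 2L)
    anatomy_classification(aligned, threshold = threshold,
                           rounds = rounds, seed = seed) else NULL
  taxa <- taxon_classification(aligned, threshold = threshold,
                               rounds = rounds, seed = seed)
  physig <- if (!is.null(tree))
    study_physignal(aligned, tree, n_perm = n_perm_k, seed = seed,
                    threshold = threshold, slide = slide) else NULL

  structure(list(aligned = aligned, anova = anova, anatomy = anatomy,
                 taxa = taxa, physignal = physig,
                 params = list(threshold = threshold, rounds = rounds,
                               n_perm_anova = n_perm_anova,
                               n_perm_k = n_perm_k, seed = seed,
                               slide = slide,
                               scheme_counts = scheme$counts_per_curve),
                 timing = proc.time()[["elapsed"]] - t0),
            class = "tooth_study_report")
}

#' @export
print.tooth_study_report <- function(x, ...) {
  cat("Dental study analysis (seed", x$params$seed, ",",
      round(x$timing, 1), "s)\n\n")
  print(x$anova)
  if (!is.null(x$anatomy))
    cat("\nAnatomical CCV:", round(x$anatomy$report$ccv, 2), "%\n")
  cat("Taxonomic CCV per tooth (%):",
      paste(sprintf("%s=%.2f", names(x$taxa),
                    vapply(x$taxa, function(t) t$report$ccv, 0)),
            collapse = ", "), "\n")
  if (!is.null(x$physignal)) print(x$physignal)
  invisible(x)
}

#' Write machine-readable pipeline outputs
#'
#' Emits the analysis tables as CSV plus a JSON run report (seeds, parameter
#' values, specimen counts, timing, package version), so runs are auditable
#' and reproducible.
#'
#' @param report an [analyze_tooth_study()] result.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_study_report <- function(report, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- character()
  wr <- function(df, name) {
    f <- file.path(outdir, name)
    utils::write.csv(df, f, row.names = TRUE)
    files <<- c(files, f)
  }
  wr(report$anova$table, "anova_table.csv")
  utils::write.csv(coords_table(report$aligned),
                   file.path(outdir, "aligned_coords.csv"), row.names = FALSE)
  files <- c(files, file.path(outdir, "aligned_coords.csv"))

  taxa_tab <- do.call(rbind, lapply(names(report$taxa), function(to) {
    t <- report$taxa[[to]]
    data.frame(tooth = to,
               pillai = if (!is.null(t$manova)) t$manova$pillai else NA,
               approx_f = if (!is.null(t$manova)) t$manova$approx_f else NA,
               p = if (!is.null(t$manova)) t$manova$p else NA,
               ccv = t$report$ccv, ccv_modal = t$report$ccv_modal)
  }))
  wr(taxa_tab, "taxon_classification.csv")
  for (to in names(report$taxa))
    wr(report$taxa[[to]]$report$confusion, paste0("confusion_", to, ".csv"))
  if (!is.null(report$anatomy))
    wr(report$anatomy$report$confusion, "confusion_anatomy.csv")

  if (!is.null(report$physignal)) {
    k_tab <- do.call(rbind, lapply(names(report$physignal), function(to)
      data.frame(tooth = to, K = report$physignal[[to]]$kmult$K,
                 p = report$physignal[[to]]$kmult$p)))
    wr(k_tab, "kmult.csv")
    for (to in names(report$physignal)) {
      pms <- report$physignal[[to]]$phylomorphospace
      wr(rbind(data.frame(node = rownames(pms$tip_coords),
                          pms$tip_coords[, 1:2, drop = FALSE]),
               data.frame(node = rownames(pms$node_coords),
                          stats::setNames(as.data.frame(pms$node_coords[, 1:2, drop = FALSE]),
                                          colnames(pms$tip_coords)[1:2]))),
         paste0("phylomorphospace_", to, "_nodes.csv"))
      wr(pms$segments, paste0("phylomorphospace_", to, "_edges.csv"))
    }
  }

  run <- list(package = "equimorph",
              version = as.character(utils::packageVersion("equimorph")),
              date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
              n_specimens = nrow(report$aligned$meta),
              n_taxa = length(unique(report$aligned$meta$taxon)),
              teeth = names(report$aligned$per_tooth),
              params = report$params,
              timing_seconds = report$timing,
              anatomical_ccv = if (!is.null(report$anatomy))
                report$anatomy$report$ccv else NULL,
              taxon_ccv = lapply(report$taxa, function(t) t$report$ccv),
              kmult = if (!is.null(report$physignal))
                lapply(report$physignal, function(t)
                  list(K = t$kmult$K, p = t$kmult$p)) else NULL)
  jf <- file.path(outdir, "run_report.json")
  jsonlite::write_json(run, jf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, jf))
}
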