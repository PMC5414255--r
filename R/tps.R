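#' Construct a digitized tooth specimen
#'
#' One digitized occlusal enamel outline: fixed landmarks plus the raw digitized
#' curves joining them, with specimen metadata. Coordinates are in image units
#' (pixels, or physical units once a scale factor has been applied).
#'
#' @param id specimen identifier (unique within a study).
#' @param landmarks numeric `n_landmarks x 2` matrix of fixed landmarks.
#' @param curves list of numeric polylines (`k x 2` matrices, `k >= 2`), one per
#'   curve, in scheme order; curve `c` is expected to start and end near its two
#'   flanking landmarks.
#' @param taxon,tooth,side metadata: taxon code, tooth position (one of
#'   `"P3","P4","M1","M2"`), and side (`"left"` or `"right"`).
#' @param scale optional units-per-pixel factor already applied to the
#'   coordinates (kept for provenance).
#' @param image optional source image name.
#' @return An object of class `tooth_specimen`.
#' @export
tooth_specimen <- function(id, landmarks, curves, taxon = NA_character_,
                           tooth = NA_character_, side = "left",
                           scale = NULL, image = NA_character_) {
  landmarks <- as.matrix(landmarks)
  if (ncol(landmarks) != 2L) stop("landmarks must be a 2-column matrix")
  if (!all(is.finite(landmarks))) stop("non-finite landmark coordinates in ", id)
  if (!is.list(curves)) stop("curves must be a list of polylines")
  curves <- lapply(curves, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != 2L || nrow(m) < 2L)
      stop("each curve must be a polyline of >= 2 points (specimen ", id, ")")
    if (!all(is.finite(m))) stop("non-finite curve coordinates in ", id)
    m
  })
  side <- match.arg(side, c("left", "right"))
  structure(list(id = as.character(id), landmarks = landmarks, curves = curves,
                 taxon = taxon, tooth = tooth, side = side,
                 scale = scale, image = image),
            class = "tooth_specimen")
}

#' @export
print.tooth_specimen <- function(x, ...) {
  cat("Tooth specimen", x$id, "—", nrow(x$landmarks), "landmarks,",
      length(x$curves), "curves; taxon:", x$taxon, "tooth:", x$tooth,
      "side:", x$side, "\n")
  invisible(x)
}

## --- TPS file format (tpsDig dialect) ---------------------------------------

#' Read a TPS landmark/curve file
#'
#' Parses the tpsDig text dialect: per-specimen blocks of `LM=` (fixed
#' landmarks), optional `CURVES=` / `POINTS=` sub-blocks (digitized polylines),
#' and trailing `IMAGE=`, `ID=`, `SCALE=` records. When `SCALE=` is present all
#' coordinates of that block are multiplied by it on input. Specimen order in
#' the file is preserved.
#'
#' @param path path to a TPS file.
#' @param metadata optional data frame with columns `specimen_id`, `taxon`,
#'   `tooth`, `side` joined onto the specimens by `ID`; every specimen must
#'   match exactly one row.
#' @return A list of [tooth_specimen] objects.
#' @seealso [write_tps()], [read_study_metadata()]
#' @export
read_tps <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("TPS file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  starts <- grep("^LM=", lines)
  if (!length(starts)) stop("no LM= records found in ", path)
  ends <- c(starts[-1L] - 1L, length(lines))

  read_points <- function(block, from, n, id) {
    if (from + n - 1L > length(block))
      stop("TPS parse error (", id, "): expected ", n,
           " coordinate lines, file block too short")
    xy <- block[from:(from + n - 1L)]
    mat <- suppressWarnings(matrix(as.numeric(unlist(strsplit(xy, "[[:space:]]+"))),
                                   ncol = 2L, byrow = TRUE))
    if (nrow(mat) != n || anyNA(mat))
      stop("TPS parse error (", id, "): malformed coordinate lines")
    mat
  }

  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    block <- lines[starts[b]:ends[b]]
    id <- sub("^ID=", "", grep("^ID=", block, value = TRUE)[1])
    if (is.na(id)) id <- paste0("specimen_", b)

    n_lm <- as.integer(sub("^LM=", "", block[1L]))
    lms <- read_points(block, 2L, n_lm, id)
    cursor <- 2L + n_lm

    curves <- list()
    cv_line <- grep("^CURVES=", block)
    if (length(cv_line)) {
      n_cv <- as.integer(sub("^CURVES=", "", block[cv_line[1L]]))
      cursor <- cv_line[1L] + 1L
      for (k in seq_len(n_cv)) {
        if (cursor > length(block) || !grepl("^POINTS=", block[cursor]))
          stop("TPS parse error (", id, "): missing POINTS= for curve ", k)
        n_pt <- as.integer(sub("^POINTS=", "", block[cursor]))
        curves[[k]] <- read_points(block, cursor + 1L, n_pt, id)
        cursor <- cursor + 1L + n_pt
      }
    }

    sc_line <- grep("^SCALE=", block, value = TRUE)
    scale <- if (length(sc_line)) as.numeric(sub("^SCALE=", "", sc_line[1L])) else NULL
    if (!is.null(scale)) {
      lms <- lms * scale
      curves <- lapply(curves, `*`, scale)
    }
    img <- sub("^IMAGE=", "", grep("^IMAGE=", block, value = TRUE)[1])

    out[[b]] <- tooth_specimen(id = id, landmarks = lms, curves = curves,
                               scale = scale, image = img)
  }

  if (!is.null(metadata)) out <- attach_metadata(out, metadata)
  out
}

#' Write specimens to a TPS file
#'
#' Emits the same tpsDig dialect that [read_tps()] consumes (`LM=`, `CURVES=`,
#' `POINTS=`, `IMAGE=`, `ID=`, `SCALE=`). Coordinates are written as stored;
#' when a specimen carries a `scale`, it is recorded but not un-applied, so a
#' read/write/read cycle reproduces coordinates only for files written by this
#' function (scale 1 semantics).
#'
#' @param specimens list of [tooth_specimen] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(specimens, path) {
  fmt <- function(m) paste(format(m[, 1L], trim = TRUE, digits = 15),
                           format(m[, 2L], trim = TRUE, digits = 15))
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in specimens) {
    writeLines(paste0("LM=", nrow(sp$landmarks)), con)
    writeLines(fmt(sp$landmarks), con)
    if (length(sp$curves)) {
      writeLines(paste0("CURVES=", length(sp$curves)), con)
      for (cv in sp$curves) {
        writeLines(paste0("POINTS=", nrow(cv)), con)
        writeLines(fmt(cv), con)
      }
    }
    if (!is.na(sp$image)) writeLines(paste0("IMAGE=", sp$image), con)
    writeLines(paste0("ID=", sp$id), con)
  }
  invisible(path)
}

#' Read a specimen metadata table
#'
#' Delimited text with header columns `specimen_id`, `taxon`, `tooth`, `side`.
#'
#' @param path path to a CSV/TSV file (delimiter auto-detected from the header).
#' @return A data frame with character columns.
#' @export
read_study_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("specimen_id", "taxon", "tooth", "side")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  md
}

#' Join metadata onto specimens
#'
#' @param specimens list of [tooth_specimen] objects.
#' @param metadata data frame as returned by [read_study_metadata()].
#' @return The specimen list with `taxon`, `tooth`, `side` filled in.
#' @export
attach_metadata <- function(specimens, metadata) {
  idx <- match(vapply(specimens, `[[`, "", "id"), metadata$specimen_id)
  if (anyNA(idx)) {
    bad <- vapply(specimens, `[[`, "", "id")[is.na(idx)]
    stop("unmatched specimen(s) in metadata: ", paste(bad, collapse = ", "))
  }
  Map(function(sp, i) {
    sp$taxon <- metadata$taxon[i]
    sp$tooth <- metadata$tooth[i]
    sp$side <- match.arg(tolower(metadata$side[i]), c("left", "right"))
    sp
  }, specimens, idx)
}

## --- geometric preprocessing -------------------------------------------------

#' Centroid size of a point configuration
#'
#' The square root of the summed squared distances of all points from their
#' centroid — the size measure removed during Procrustes superimposition.
#'
#' @param x numeric `p x 2` matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(x) {
  x <- as.matrix(x)
  cs <- sqrt(sum(sweep(x, 2L, colMeans(x))^2))
  if (cs == 0) stop("degenerate configuration: all points identical (zero centroid size)")
  cs
}

#' Mirror a right-side specimen to the left
#'
#' Digitization protocols standardize on one side; right-side configurations
#' are reflected about a vertical axis through their centroid so that left and
#' right teeth become comparable. Reflection about the centroid keeps the
#' configuration in place (positive quadrant preserved for positive input) and
#' is an isometry, so centroid size and all inter-point distances are
#' unchanged. Point and curve ordering are untouched.
#'
#' @param spec a [tooth_specimen]; should have `side == "right"`.
#' @return The mirrored specimen with `side` set to `"left"`. Applying to an
#'   already-left specimen warns and returns it unchanged.
#' @export
mirror_to_left <- function(spec) {
  if (spec$side == "left") {
    warning("specimen ", spec$id, " is already left-sided; mirror_to_left is a no-op")
    return(spec)
  }
  all_x <- c(spec$landmarks[, 1L], unlist(lapply(spec$curves, `[`, , 1L)))
  cx <- mean(range(all_x))
  flip <- function(m) { m[, 1L] <- 2 * cx - m[, 1L]; m }
  spec$landmarks <- flip(spec$landmarks)
  spec$curves <- lapply(spec$curves, flip)
  spec$side <- "left"
  spec
}

## arc-length resampling of one polyline: k points strictly between the ends,
## equally spaced at fractions i/(k+1) of total arc length
resample_polyline <- function(poly, k) {
  seg <- sqrt(rowSums(diff(poly)^2))
  L <- sum(seg)
  if (L <= 0) stop("degenerate (zero-length) curve cannot be resampled")
  cum <- c(0, cumsum(seg))
  targets <- L * seq_len(k) / (k + 1)
  out <- matrix(0, k, 2L)
  for (i in seq_len(k)) {
    j <- findInterval(targets[i], cum, rightmost.closed = TRUE)
    j <- min(j, length(seg))
    t <- (targets[i] - cum[j]) / seg[j]
    out[i, ] <- poly[j, ] + t * (poly[j + 1L, ] - poly[j, ])
  }
  out
}

#' Resample digitized curves into equidistant semi-landmarks
#'
#' Each raw curve polyline is replaced by the scheme's number of semi-landmarks
#' for that curve, equally spaced in arc length along the polyline and
#' excluding the flanking fixed landmarks. The result is a flat configuration
#' in scheme point order (landmarks first, then curves).
#'
#' @param spec a [tooth_specimen] whose curve count matches the scheme.
#' @param scheme a [slider_scheme].
#' @param skip_resample if `TRUE` and every curve already contains exactly the
#'   scheme's semi-landmark count, curve points are taken as-is (for files
#'   digitized directly at the scheme density).
#' @return numeric `p x 2` configuration matrix.
#' @export
resample_curves <- function(spec, scheme, skip_resample = FALSE) {
  if (length(spec$curves) != length(scheme$counts_per_curve))
    stop("specimen ", spec$id, " has ", length(spec$curves),
         " curves; scheme expects ", length(scheme$counts_per_curve))
  if (nrow(spec$landmarks) != scheme$n_landmarks)
    stop("specimen ", spec$id, " landmark count does not match scheme")
  semis <- vector("list", length(spec$curves))
  for (cv in seq_along(spec$curves)) {
    k <- scheme$counts_per_curve[cv]
    if (skip_resample && nrow(spec$curves[[cv]]) == k) {
      semis[[cv]] <- spec$curves[[cv]]
    } else {
      semis[[cv]] <- resample_polyline(spec$curves[[cv]], k)
    }
  }
  config <- rbind(spec$landmarks, do.call(rbind, semis))
  rownames(config) <- NULL
  config
}
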