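test_that("default digitization scheme totals 178 semi-landmarks and 186 points", {
  sch <- slider_scheme()
  expect_identical(sch$n_semilandmarks, 178L)
  expect_identical(sch$p, 186L)
  expect_identical(sum(sch$counts_per_curve), 178L)
})

test_that("slider triplets chain each semi-landmark between its curve neighbours", {
  sch <- slider_scheme(c(2L, 2L, 2L, 2L, 2L, 2L, 3L, 3L))
  ## every semi-landmark is the middle of exactly one triplet
  expect_identical(sort(sch$sliders[, "slider"]), sch$semilandmark_index)
  ## first semi-landmark of curve 1 is anchored on landmark 1
  expect_identical(sch$sliders[1, ], c(before = 1L, slider = 9L, after = 10L))
  ## last semi-landmark of the last curve is anchored on landmark 1 (closure)
  m <- nrow(sch$sliders)
  expect_identical(unname(sch$sliders[m, "after"]), 1L)
  ## neighbours are adjacent along the chain: consecutive flat indices inside
  ## a curve, landmarks at the ends
  inner <- sch$sliders[sch$sliders[, "before"] > sch$n_landmarks, ]
  expect_true(all(inner[, "slider"] - inner[, "before"] == 1L))
})

test_that("TPS write/read round-trips coordinates, IDs and metadata join works", {
  sch <- tiny_scheme()
  st <- fixture_study(seed = 11, scheme = sch)
  specs <- st$specimens[1:2]
  tf <- withr::local_tempfile(fileext = ".tps")
  write_tps(specs, tf)
  back <- read_tps(tf)
  expect_identical(vapply(back, `[[`, "", "id"), vapply(specs, `[[`, "", "id"))
  for (i in 1:2) {
    expect_equal(back[[i]]$landmarks, specs[[i]]$landmarks, tolerance = 1e-12)
    expect_equal(back[[i]]$curves, specs[[i]]$curves, tolerance = 1e-12)
  }
  md <- st$metadata[1:2, ]
  joined <- attach_metadata(back, md)
  expect_identical(joined[[1]]$taxon, md$taxon[1])
  expect_identical(joined[[2]]$tooth, md$tooth[2])
  expect_error(attach_metadata(back, md[1, , drop = FALSE]), "unmatched specimen")
})

test_that("SCALE= multiplies coordinates and malformed blocks raise parse errors", {
  tf <- withr::local_tempfile(fileext = ".tps")
  writeLines(c("LM=3", "10 4", "0 0", "2 2", "SCALE=0.5", "ID=sp1"), tf)
  sp <- read_tps(tf)[[1]]
  expect_equal(sp$landmarks[1, ], c(5, 2))
  expect_equal(sp$landmarks[3, ], c(1, 1))

  writeLines(c("LM=5", "10 4", "0 0", "ID=bad1"), tf)
  expect_error(read_tps(tf), "bad1")
  writeLines(c("LM=2", "1 1", "2 2", "CURVES=1", "1 1", "ID=bad2"), tf)
  expect_error(read_tps(tf), "POINTS")
})

test_that("mirroring is an involution and an isometry preserving centroid size", {
  st <- fixture_study(seed = 12, scheme = tiny_scheme())
  sp <- st$specimens[[which(vapply(st$specimens, `[[`, "", "side") == "right")[1]]]
  m <- mirror_to_left(sp)
  expect_identical(m$side, "left")
  ## distances between all landmarks preserved
  expect_equal(c(dist(m$landmarks)), c(dist(sp$landmarks)), tolerance = 1e-12)
  expect_equal(centroid_size(m$landmarks), centroid_size(sp$landmarks),
               tolerance = 1e-12)
  ## mirror twice = original (up to the translation convention, which is
  ## centroid-preserving, so coordinates return exactly)
  m$side <- "right"
  mm <- mirror_to_left(m)
  expect_equal(mm$landmarks, sp$landmarks, tolerance = 1e-9)
  expect_equal(mm$curves[[3]], sp$curves[[3]], tolerance = 1e-9)
  expect_warning(mirror_to_left(mm), "no-op")
})

test_that("curve resampling places equidistant points (line and semicircle oracle)", {
  ## straight segment: 4 semi-landmarks at x = 2, 4, 6, 8
  poly <- cbind(seq(0, 10, length.out = 7), 0)
  pts <- equimorph:::resample_polyline(poly, 4L)
  expect_equal(pts[, 1], c(2, 4, 6, 8), tolerance = 1e-12)
  expect_equal(pts[, 2], rep(0, 4), tolerance = 1e-12)

  ## dense semicircle: compare against 10x-denser numeric arc-length oracle
  th <- seq(0, pi, length.out = 200)
  semi <- cbind(cos(th), sin(th))
  got <- equimorph:::resample_polyline(semi, 5L)
  th10 <- seq(0, pi, length.out = 2000)
  dense <- cbind(cos(th10), sin(th10))
  want <- equimorph:::resample_polyline(dense, 5L)
  expect_lt(max(abs(got - want)), 1e-3)
})

test_that("centroid size follows the root-sum-of-squares definition", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), ncol = 2, byrow = TRUE)
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  expect_equal(centroid_size(3.7 * sq), 3.7 * sqrt(2), tolerance = 1e-12)
  expect_equal(centroid_size(sweep(sq, 2, c(100, -40), `+`)), sqrt(2),
               tolerance = 1e-12)
  expect_error(centroid_size(matrix(1, 4, 2)), "zero")
})
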