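test_that("state covariances realise the requested block structure", {
  atlas <- buildAtlas(c(M = 4L))
  # uniform zero correlation -> identity
  id <- makeStateCovariances(atlas, list(list(
    name = "null", tag = "unstructured", modules = character(0),
    within = 0, between = 0, homotopic = NA_real_, base = 0)))[[1]]
  expect_equal(unname(id@covariance), diag(4), tolerance = 1e-12,
               ignore_attr = TRUE)

  # single module, rho_within = 0.6 -> all off-diagonals 0.6
  one <- makeStateCovariances(atlas, list(list(
    name = "m", tag = "modular", modules = "M", within = 0.6, between = 0.6,
    homotopic = NA_real_, base = 0)))[[1]]
  v <- one@covariance
  expect_equal(unname(v[upper.tri(v)]), rep(0.6, 6), tolerance = 1e-12)
})

test_that("non-PSD block constructions are projected to a PSD correlation", {
  atlas <- buildAtlas(c(M = 4L))
  # strong homotopic with weak within-module coupling is not PSD as written
  st <- makeStateCovariances(atlas, list(list(
    name = "h", tag = "homotopic", modules = "M", within = 0.3, between = 0.3,
    homotopic = 0.95, base = 0)))[[1]]
  ev <- eigen(st@covariance, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(unname(diag(st@covariance)), rep(1, 4), tolerance = 1e-8)
  # default states are all PSD and carry their projection distance
  states <- makeStateCovariances(buildAtlas())
  for (s in states) {
    expect_gte(min(eigen(s@covariance, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-8)
    expect_true(!is.null(attr(s@covariance, "psd_distance")))
  }
})

test_that("state sequences honour degenerate and bounded cases", {
  s <- sampleStateSequence(100L, c(1, 0), dwellMean = 10, seed = 3)
  expect_equal(as.integer(s), rep(1L, 100L))

  s2 <- sampleStateSequence(360L, c(0.5, 0.3, 0.2), dwellMean = 40, seed = 5)
  expect_length(s2, 360L)
  expect_true(all(s2 %in% 1:3))
  seg <- attr(s2, "segments")
  expect_gte(nrow(seg), 1L)
  expect_lte(nrow(seg), 360L)
  expect_equal(sum(seg[, "length"]), 360L)
})

test_that("label frequencies match occupancy (quota exactly, free-run in the long run)", {
  occ <- c(0.5, 0.5)
  sq <- sampleStateSequence(100000L, occ, dwellMean = 40, seed = 11)
  expect_equal(as.numeric(table(sq)) / 100000, c(0.5, 0.5), tolerance = 1e-6)
  sf <- sampleStateSequence(100000L, occ, dwellMean = 40, seed = 11,
                            quota = FALSE)
  expect_lt(abs(mean(sf == 1) - 0.5), 0.02)
  # quota matches a non-trivial simplex to rounding at realistic T
  occ6 <- c(0.25, 0.23, 0.16, 0.12, 0.14, 0.10)
  q <- sampleStateSequence(360L, occ6, dwellMean = 40, seed = 2)
  expect_lt(max(abs(as.numeric(table(factor(q, levels = 1:6))) / 360 - occ6)),
            1.01 / 360)
})

test_that("a single identity state yields uncorrelated columns", {
  atlas <- tinyAtlas()
  states <- makeStateCovariances(atlas, list(list(
    name = "id", tag = "unstructured", modules = character(0), within = 0,
    between = 0, homotopic = NA_real_, base = 0)))
  cfg <- cohortConfig(nSubjects = 1L, doses = 1.1, nTimepoints = 10000L,
                      homotopicRho = c("1.1" = 0.5),
                      occupancy = matrix(1, 1, 1), noiseSd = 0, hrfFwhm = 0,
                      subjectEffectSd = 0, seed = 1L)
  ts <- simulateSubject(atlas, states, rep.int(1L, 10000L), 1.1, cfg, seed = 9)
  cc <- cor(seriesMatrix(ts))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)  # ~4 SE at T = 1e4
})

test_that("homotopic correlation is recovered within the sampling envelope", {
  atlas <- tinyAtlas()
  specs <- list(list(name = "h", tag = "homotopic",
                     modules = unique(moduleOf(atlas)), within = 0.2,
                     between = 0.1, homotopic = 0.7, base = 0.1))
  states <- makeStateCovariances(atlas, specs)
  cfg <- cohortConfig(nSubjects = 1L, doses = 1.1, nTimepoints = 360L,
                      homotopicRho = c("1.1" = 0.7),
                      occupancy = matrix(1, 1, 1), noiseSd = 0, hrfFwhm = 0,
                      subjectEffectSd = 0, seed = 1L)
  ts <- simulateSubject(atlas, states, rep.int(1L, 360L), 1.1, cfg, seed = 21)
  fc <- fullCorrelation(ts)
  hom <- homotopicEdges(fc, atlas)
  # target after PSD projection of the requested blocks
  target <- mean(homotopicEdges(
    new("FCMatrix", values = states[[1]]@covariance, kind = "full",
        scale = "r"), atlas))
  expect_lt(max(abs(hom - target)), 0.15)
})

test_that("simulation is bit-reproducible under a fixed seed", {
  atlas <- tinyAtlas()
  states <- makeStateCovariances(atlas, list(list(
    name = "s", tag = "modular", modules = "A", within = 0.4, between = 0.2,
    homotopic = 0.6, base = 0.05)))
  cfg <- cohortConfig(nSubjects = 1L, doses = 1.1, nTimepoints = 120L,
                      homotopicRho = c("1.1" = 0.6),
                      occupancy = matrix(1, 1, 1), seed = 1L)
  a <- simulateSubject(atlas, states, rep.int(1L, 120L), 1.1, cfg, seed = 77)
  b <- simulateSubject(atlas, states, rep.int(1L, 120L), 1.1, cfg, seed = 77)
  expect_identical(seriesMatrix(a), seriesMatrix(b))
  expect_error(simulateSubject(atlas, states, rep.int(1L, 120L), 9.9, cfg),
               "homotopicRho")
})

test_that("cohorts carry the right counts and echo ground truth", {
  cfg <- tinyCohortConfig(seed = 5L)
  coh <- simulateCohort(cfg)
  expect_length(coh$subjects, 2L * 3L)
  expect_length(coh$truth$sequences, 6L)
  expect_equal(coh$truth$homotopicRho, cfg@homotopicRho)
  expect_equal(coh$truth$occupancy, cfg@occupancy)
  # longitudinal design reuses subject ids across doses
  ids <- vapply(coh$subjects, subjectId, character(1))
  expect_equal(sort(unique(ids)), c("s01", "s02", "s03"))

  # identical config -> identical bytes after writing
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeCohort(coh, d1)
  writeCohort(simulateCohort(tinyCohortConfig(seed = 5L)), d2)
  f1 <- list.files(d1, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)),
                   unname(tools::md5sum(file.path(d2, basename(f1)))))
})

test_that("cohort TSV round trip preserves data and metadata", {
  coh <- simulateCohort(tinyCohortConfig(seed = 8L))
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  back <- readCohort(dir)
  expect_length(back$subjects, length(coh$subjects))
  tag <- names(coh$subjects)[1]
  orig <- coh$subjects[[tag]]
  got <- back$subjects[[tag]]
  expect_equal(seriesMatrix(got), seriesMatrix(orig), tolerance = 1e-8)
  expect_equal(dose(got), dose(orig))
  expect_equal(repetitionTime(got), repetitionTime(orig))
  expect_equal(regionLabels(back$atlas), regionLabels(coh$atlas))
})
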