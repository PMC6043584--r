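test_that("high-pass filter removes constants and slow ramps, keeps fast oscillations", {
  T <- 360L
  const <- matrix(5, T, 1, dimnames = list(NULL, "c"))
  ramp <- matrix(seq_len(T) * 0.3, T, 1, dimnames = list(NULL, "ramp"))
  fast <- matrix(sin(2 * pi * seq_len(T) / 10), T, 1, dimnames = list(NULL, "sin"))
  ts <- subjectTimeSeries(cbind(const, ramp, fast) +
                            matrix(0, T, 3), tr = 1)
  colnames(ts@values) <- c("c", "ramp", "sin")
  out <- seriesMatrix(highpassFilter(ts, sigmaS = 75))
  expect_lt(max(abs(out[, "c"])), 1e-10)
  # residual slope under 1% of the input slope
  slope <- coef(lm(out[, "ramp"] ~ seq_len(T)))[2]
  expect_lt(abs(slope), 0.01 * 0.3)
  # 10 s period passes nearly untouched: amplitude within 5%
  amp <- sqrt(2 * mean(out[, "sin"]^2))
  expect_equal(amp, sqrt(2 * mean(fast^2)), tolerance = 0.05)
  expect_lt(max(abs(colMeans(out))), 1e-10)
})

test_that("high-pass warns when the kernel degenerates to demeaning", {
  ts <- subjectTimeSeries(namedMatrix(60L, 2L), tr = 1)
  expect_warning(highpassFilter(ts, sigmaS = 1.5), "demean")
})

test_that("variance normalisation gives unit variance and is idempotent", {
  ts <- subjectTimeSeries(namedMatrix(80L, 3L, seed = 4), tr = 1)
  vn <- varianceNormalize(ts)
  expect_equal(unname(apply(seriesMatrix(vn), 2, var)), rep(1, 3),
               tolerance = 1e-12)
  expect_equal(unname(colMeans(seriesMatrix(vn))), rep(0, 3), tolerance = 1e-12)
  vn2 <- varianceNormalize(vn)
  expect_equal(seriesMatrix(vn2), seriesMatrix(vn), tolerance = 1e-12)

  bad <- namedMatrix(30L, 2L)
  bad[, 2] <- 7
  expect_error(varianceNormalize(subjectTimeSeries(bad, tr = 1)), "r2")
})

test_that("reapplying highpass + variance-normalise is a near no-op", {
  # the Gaussian-weighted running-line filter is not a projection, so exact
  # idempotence cannot hold; its side-lobe response is a few percent, and a
  # second application must stay within that envelope
  ts <- tinySubject(T = 360L, seed = 6)
  once <- varianceNormalize(highpassFilter(ts, 75))
  twice <- varianceNormalize(highpassFilter(once, 75))
  relChange <- sqrt(sum((seriesMatrix(twice) - seriesMatrix(once))^2) /
                      sum(seriesMatrix(once)^2))
  expect_lt(relChange, 0.05)
  # correlation structure, the quantity every later stage consumes, is stable
  expect_equal(cor(seriesMatrix(twice)), cor(seriesMatrix(once)),
               tolerance = 1e-3)
})

test_that("dual regression recovers planted time courses with orthogonal maps", {
  set.seed(10)
  V <- 60L; C <- 3L; T <- 40L
  maps <- qr.Q(qr(matrix(rnorm(V * C), V, C)))  # orthonormal columns
  M <- t(maps)                                   # C x V
  A <- matrix(rnorm(T * C), T, C)
  data <- A %*% M
  dr <- dualRegression(M, data, normalize = FALSE)
  expect_equal(abs(diag(cor(dr$timeCourses, A))), rep(1, C), tolerance = 1e-8)
  # noiseless rank-C data reconstructs to machine precision
  recon <- dr$timeCourses %*% dr$subjectMaps
  expect_equal(recon, data, tolerance = 1e-8)
})

test_that("dual regression stage 2 equals the projection identity for orthonormal TCs", {
  set.seed(11)
  V <- 50L; C <- 2L; T <- 30L
  M <- matrix(rnorm(C * V), C, V)
  data <- matrix(rnorm(T * V), T, V)
  dr <- dualRegression(M, data)
  tc <- dr$timeCourses
  # with centred, variance-normalised TCs the stage-2 solution solves the
  # normal equations exactly
  Z <- cbind(1, tc)
  beta <- solve(crossprod(Z), crossprod(Z, data))
  expect_equal(dr$subjectMaps, beta[-1, , drop = FALSE], tolerance = 1e-10,
               ignore_attr = TRUE)
  # stage-1 residuals orthogonal to the map span
  X1 <- cbind(1, t(M))
  fitted <- X1 %*% qr.coef(qr(X1), t(data))
  expect_lt(max(abs(crossprod(X1, t(data) - fitted))), 1e-8)
})

test_that("rank-deficient group maps are rejected with a condition number", {
  M <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8))
  data <- matrix(rnorm(20), 5, 4)
  expect_error(dualRegression(M, data), "condition number")
  expect_error(dualRegression(matrix(1, 2, 3), matrix(1, 4, 7)), "voxel")
})

test_that("NIfTI 4-D round trip preserves the time x voxel matrix", {
  mat <- matrix(rnorm(6 * 24), 6, 24)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeNifti4DMatrix(mat, c(2L, 3L, 4L), path)
  back <- readNifti4DMatrix(path)
  expect_equal(unname(back[seq_len(6), ]), mat, tolerance = 1e-6)
  expect_equal(attr(back, "voldim"), c(2L, 3L, 4L))
})
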