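mkDict <- function(D, tag = "t") {
  new("StateDictionary", atoms = D / sqrt(rowSums(D^2)),
      foldCount = 1L, stability = rep(1, nrow(D)), orderingTag = tag,
      objective = numeric(0), lambda = 0)
}

test_that("back-fit recovers exact codes and obeys projection identities", {
  set.seed(60)
  D <- matrix(rnorm(4 * 20), 4, 20)
  dict <- mkDict(D)
  Atrue <- matrix(rnorm(50 * 4), 50, 4)
  X <- Atrue %*% atoms(dict)
  wt <- backfitWeights(dict, X)
  expect_equal(unname(weightMatrix(wt)), Atrue, tolerance = 1e-10)
  expect_equal(weightSummary(wt), colMeans(abs(Atrue)), tolerance = 1e-10,
               ignore_attr = TRUE)

  # orthonormal atoms: weights are plain inner products
  Q <- qr.Q(qr(matrix(rnorm(20 * 3), 20, 3)))
  dictQ <- mkDict(t(Q))
  Xq <- matrix(rnorm(30 * 20), 30, 20)
  wq <- backfitWeights(dictQ, Xq)
  expect_equal(unname(weightMatrix(wq)), Xq %*% Q, tolerance = 1e-10)

  # noisy stack: residuals orthogonal to the atom span
  Xn <- X + matrix(rnorm(length(X), sd = 0.5), nrow(X))
  wn <- backfitWeights(dict, Xn)
  resid <- Xn - weightMatrix(wn) %*% atoms(dict)
  expect_lt(max(abs(atoms(dict) %*% t(resid))), 1e-8)
})

test_that("rank-deficient dictionaries are rejected with a condition number", {
  D <- rbind(c(1, 0, 0, 0), c(1, 1e-9, 0, 0))
  expect_error(backfitWeights(mkDict(D), matrix(rnorm(12), 3, 4)),
               "condition number")
  expect_error(backfitWeights(mkDict(diag(3)), matrix(rnorm(8), 2, 4)),
               "edge sets differ")
})

test_that("back-fit scales linearly with the stack", {
  set.seed(61)
  D <- matrix(rnorm(3 * 10), 3, 10)
  dict <- mkDict(D)
  X <- matrix(rnorm(20 * 10), 20, 10)
  w1 <- weightMatrix(backfitWeights(dict, X))
  w3 <- weightMatrix(backfitWeights(dict, 3 * X))
  expect_equal(w3, 3 * w1, tolerance = 1e-12)
})

test_that("variance explained is 1 for perfect fits and clamped at 0", {
  set.seed(62)
  D <- matrix(rnorm(3 * 12), 3, 12)
  dict <- mkDict(D)
  X <- matrix(rnorm(25 * 3), 25, 3) %*% atoms(dict)
  expect_equal(as.numeric(varianceExplained(dict, X)), 1, tolerance = 1e-10)
  # stack entirely orthogonal to the dictionary span (fit is exactly zero):
  # the uncentred residual exceeds the centred total, so VE < 0 -> clamped
  Q <- qr.Q(qr(t(atoms(dict))), complete = TRUE)[, 4:12]
  Xo <- matrix(rnorm(25 * 9), 25, 9) %*% t(Q) +
    outer(rep(1, 25), 5 * Q[, 1])
  ve <- varianceExplained(dict, Xo)
  expect_equal(as.numeric(ve), 0)
  expect_true(isTRUE(attr(ve, "clamped")))
  expect_error(varianceExplained(dict, matrix(2, 10, 12)), "constant")
})

test_that("variance explained is non-decreasing in K for nested dictionaries", {
  set.seed(63)
  X <- matrix(rnorm(120 * 21), 120, 21)
  D <- matrix(rnorm(12 * 21), 12, 21)
  ve <- vapply(c(4L, 8L, 12L), function(k)
    as.numeric(varianceExplained(mkDict(D[seq_len(k), , drop = FALSE]), X)),
    numeric(1))
  expect_true(all(diff(ve) >= -1e-12))
})

test_that("state ranking sorts by mean summary with index tie-break", {
  expect_equal(rankStates(matrix(c(3, 1, 2), 1)), c(1L, 3L, 2L))
  expect_equal(rankStates(matrix(1, 4, 3)), 1:3)
  set.seed(64)
  sm <- rbind(c(0.2, 0.9, 0.4), c(0.1, 0.8, 0.5))
  expect_equal(rankStates(sm), c(2L, 3L, 1L))
})

test_that("weight comparison matches the textbook two-sample t and guards tags", {
  a <- matrix(c(1.1, 1.3, 0.9, 2.0, 2.2, 1.8), 3, 2)
  b <- matrix(c(0.8, 1.0, 0.6, 2.1, 1.9, 2.3), 3, 2)
  cw <- compareWeights(a, b)
  for (k in 1:2) {
    tt <- t.test(a[, k], b[, k], var.equal = TRUE)
    expect_equal(cw$t[k], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(cw$p[k], tt$p.value, tolerance = 1e-12)
  }
  expect_equal(cw$q_fdr, p.adjust(cw$p, "BH"))
  # identical groups: t = 0, q = 1
  cw0 <- compareWeights(a, a)
  expect_equal(cw0$t, rep(0, 2))
  expect_equal(cw0$q_fdr, rep(1, 2))
  # mismatched ordering tags must fail
  D <- matrix(rnorm(2 * 6), 2, 6)
  X <- matrix(rnorm(10 * 6), 10, 6)
  w1 <- backfitWeights(mkDict(D, "tagA"), X)
  w2 <- backfitWeights(mkDict(D, "tagB"), X)
  expect_error(compareWeights(list(w1, w1), list(w2, w2)), "tags differ")
})

test_that("a planted summary shift is detected at FDR 0.01 with others controlled", {
  set.seed(65)
  nrep <- 60L
  hit <- 0L; false <- 0L
  for (r in seq_len(nrep)) {
    a <- matrix(rnorm(12 * 10, mean = 5), 12, 10)
    b <- matrix(rnorm(12 * 10, mean = 5), 12, 10)
    a[, 4] <- a[, 4] + 2          # 2 pooled-SD shift on one atom
    cw <- compareWeights(a, b)
    hit <- hit + (cw$q_fdr[4] < 0.01)
    false <- false + sum(cw$q_fdr[-4] < 0.01)
  }
  expect_gte(hit / nrep, 0.8)
  expect_lte(false / nrep, 0.2)
})
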