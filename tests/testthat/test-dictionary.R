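test_that("planted orthogonal patterns are recovered from clean mixtures", {
  set.seed(50)
  d1 <- c(rep(1, 15), rep(0, 15)); d1 <- d1 / sqrt(sum(d1^2))
  d2 <- c(rep(0, 15), rep(1, 15)); d2 <- d2 / sqrt(sum(d2^2))
  # each window is a positive multiple of one pattern (state-dominated rows)
  X <- rbind(outer(rexp(100) + 0.2, d1), outer(rexp(100) + 0.2, d2))
  dict <- learnDictionary(X, K = 2L, nIter = 50L, seed = 1)
  S <- abs(cosineSimilarity(rbind(d1, d2), atoms(dict)))
  expect_gt(max(S[1, ]), 0.99)
  expect_gt(max(S[2, ]), 0.99)
})

test_that("a complete basis with no penalty reconstructs exactly", {
  set.seed(51)
  E <- 8L
  X <- matrix(rnorm(40 * E), 40, E)
  init <- diag(E)                      # orthonormal initial atoms
  dict <- learnDictionary(X, K = E, nIter = 60L, lambda = 0, seed = 1,
                          init = init)
  wt <- backfitWeights(dict, X)
  recon <- weightMatrix(wt) %*% atoms(dict)
  expect_lt(max(abs(recon - X)), 1e-8)
})

test_that("the learning objective is non-increasing across iterations", {
  set.seed(52)
  X <- matrix(rnorm(150 * 20), 150, 20)
  dict <- learnDictionary(X, K = 5L, nIter = 200L, seed = 3,
                          recordObjective = TRUE)
  obj <- dict@objective
  expect_length(obj, 200L)
  expect_true(all(diff(obj) <= 1e-8 * pmax(abs(obj[-length(obj)]), 1)))
  # atoms come out unit-energy
  expect_equal(unname(sqrt(rowSums(atoms(dict)^2))), rep(1, 5),
               tolerance = 1e-9)
})

test_that("Hungarian assignment equals the exhaustive-permutation optimum", {
  set.seed(53)
  for (n in c(3L, 4L, 6L)) {
    for (rep in 1:5) {
      cost <- matrix(runif(n * n), n, n)
      assign <- dfcstates:::hungarianSolve(cost)
      expect_equal(sort(assign), 1:n)
      best <- min(apply(allPerms(n), 1, function(p)
        sum(cost[cbind(1:n, p)])))
      expect_equal(sum(cost[cbind(1:n, assign)]), best, tolerance = 1e-12)
    }
  }
})

test_that("atom matching recovers identity, shuffles and sign flips", {
  set.seed(54)
  D <- matrix(rnorm(4 * 12), 4, 12)
  D <- D / sqrt(rowSums(D^2))
  m <- matchAtoms(D, D)
  expect_equal(m$permutation, 1:4)
  expect_equal(m$scores, rep(1, 4), tolerance = 1e-12)
  perm <- c(3L, 1L, 4L, 2L); flips <- c(1, -1, -1, 1)
  Db <- D[perm, ] * flips[perm]       # Db[j, ] = flips[perm[j]] * D[perm[j], ]
  m2 <- matchAtoms(D, Db)
  expect_equal(m2$permutation, order(perm))
  expect_equal(m2$signs, flips, tolerance = 1e-12)
  expect_equal(m2$scores, rep(1, 4), tolerance = 1e-12)
  # matched total equals the brute-force maximum at K = 4
  Dc <- matrix(rnorm(4 * 12), 4, 12)
  m3 <- matchAtoms(D, Dc)
  S <- abs(suppressWarnings(cor(t(D), t(Dc))))
  best <- max(apply(allPerms(4L), 1, function(p)
    sum(S[cbind(1:4, p)])))
  expect_equal(m3$total, best, tolerance = 1e-12)
})

test_that("consensus of identical folds is the first fold with stability 1", {
  set.seed(55)
  X <- matrix(rnorm(100 * 15), 100, 15)
  f <- learnDictionary(X, K = 4L, nIter = 30L, seed = 2)
  cons <- consensusDictionary(list(f, f, f), tag = "t")
  expect_equal(atoms(cons), atoms(f), tolerance = 1e-10)
  expect_equal(stability(cons), rep(1, 4), tolerance = 1e-12)
  expect_equal(cons@foldCount, 3L)
  one <- consensusDictionary(list(f))
  expect_equal(atoms(one), atoms(f))
  expect_equal(stability(one), rep(1, 4))
})

test_that("consensus over early-stopped folds beats the median single fold", {
  # noisy planted dictionary, folds stopped before convergence so their
  # solutions genuinely differ; Hungarian-aligned averaging should denoise
  set.seed(200)
  Ktrue <- 4L; E <- 40L
  truth <- matrix(rnorm(Ktrue * E), Ktrue, E)
  truth <- truth / sqrt(rowSums(truth^2))
  lab <- sample.int(Ktrue, 300, replace = TRUE)
  codes <- matrix(0, 300, Ktrue)
  codes[cbind(1:300, lab)] <- rexp(300) + 0.3
  X <- codes %*% truth + matrix(rnorm(300 * E, sd = 0.4), 300, E)
  folds <- lapply(1:10, function(f)
    learnDictionary(X, K = Ktrue, nIter = 12L, seed = f))
  cons <- consensusDictionary(folds)
  score <- function(d) mean(apply(abs(cosineSimilarity(truth, atoms(d))), 1, max))
  foldScores <- vapply(folds, score, numeric(1))
  expect_gte(score(cons), median(foldScores))
  expect_gte(score(cons), 0.9)
  expect_true(all(stability(cons) > 0 & stability(cons) <= 1))
})

test_that("atomMatrix refolds an atom into a symmetric matrix", {
  set.seed(57)
  X <- matrix(rnorm(50 * 10), 50, 10)   # 10 edges -> 5 regions
  d <- learnDictionary(X, K = 3L, nIter = 10L, seed = 1)
  m <- atomMatrix(d, 1L, labels = letters[1:5])
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 5))
  expect_equal(unname(vecUpperTri(m)), unname(atoms(d)[1, ]))
})
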