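# Shared fixtures, all generated in code.

# 6-region toy atlas: two modules, three homotopic pairs
tinyAtlas <- function() {
  buildAtlas(c(A = 4L, B = 2L))
}

# subject with a fixed covariance, no smoothing/noise unless asked
tinySubject <- function(atlas = tinyAtlas(), rho = 0.5, T = 200L, seed = 1L,
                        hrfFwhm = 0, noiseSd = 0) {
  specs <- list(list(name = "s", tag = "modular",
                     modules = unique(moduleOf(atlas)), within = rho,
                     between = rho, homotopic = rho, base = rho))
  states <- makeStateCovariances(atlas, specs)
  cfg <- cohortConfig(nSubjects = 1L, doses = 1.1, nTimepoints = T,
                      homotopicRho = c("1.1" = 0.5),
                      occupancy = matrix(1, 1, 1), noiseSd = noiseSd,
                      hrfFwhm = hrfFwhm, subjectEffectSd = 0, seed = seed)
  simulateSubject(atlas, states, rep.int(1L, T), 1.1, cfg, seed = seed)
}

# small two-dose cohort for pipeline-level tests
tinyCohortConfig <- function(seed = 1L, T = 120L, n = 3L) {
  cohortConfig(nSubjects = n, doses = c(1.1, 2.0), nTimepoints = T,
               seed = seed)
}

# deterministic T x R matrix with labelled columns
namedMatrix <- function(T = 50L, R = 4L, seed = 1L) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(T * R), T, R)
    colnames(m) <- paste0("r", seq_len(R))
    m
  })
}

# the default-conditions cohort and its learned dictionary, computed once
# and shared across acceptance tests (lazy cache)
.acceptCache <- new.env(parent = emptyenv())

acceptanceFixture <- function() {
  if (!is.null(.acceptCache$fix)) return(.acceptCache$fix)
  coh <- simulateCohort(cohortConfig(seed = 2024L))
  pre <- lapply(coh$subjects, function(ts)
    varianceNormalize(highpassFilter(ts)))
  stacks <- lapply(pre, slidingWindowFC, windowLength = 40L, step = 1L)
  pooled <- poolStacks(stacks)
  dict <- learnConsensusDictionary(pooled, K = 20L, folds = 6L,
                                   nIter = 100L, seed = 2024L)
  doseOf <- vapply(pre, dose, numeric(1))
  wts <- lapply(stacks, function(s) backfitWeights(dict, s))
  .acceptCache$fix <- list(cohort = coh, pre = pre, stacks = stacks,
                           pooled = pooled, dict = dict, weights = wts,
                           doseOf = doseOf)
  .acceptCache$fix
}

# all permutations of 1..n as rows (for exhaustive assignment oracles)
allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}
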