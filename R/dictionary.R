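#' StateDictionary: learned dynamic functional states
#'
#' K unit-energy connectivity atoms (dynamic functional states, dFS): each
#' atom is a unit-l2-norm vector over the edge set, the basis patterns whose
#' weights fluctuate across sliding windows. Carries provenance: how many
#' folds were consensused, the per-atom fold-stability score (mean |match
#' correlation| across folds), and an ordering tag that must agree between
#' dictionaries whose weights are compared.
#'
#' @slot atoms K x E numeric matrix, columns named by edge.
#' @slot foldCount number of folds merged into this dictionary.
#' @slot stability per-atom mean match score across folds.
#' @slot orderingTag string stamping the fixed atom ordering.
#' @slot objective per-iteration objective of the learning run (single fold).
#' @slot lambda l1 penalty used.
#'
#' @aliases atoms stability orderingTag
#' @export
setClass("StateDictionary",
  representation(atoms = "matrix", foldCount = "integer",
                 stability = "numeric", orderingTag = "character",
                 objective = "numeric", lambda = "numeric"))

setValidity("StateDictionary", function(object) {
  msg <- NULL
  nrm <- sqrt(rowSums(object@atoms^2))
  if (any(abs(nrm - 1) > 1e-6))
    msg <- c(msg, "atoms must have unit l2 norm (energy bounded)")
  if (length(object@stability) != nrow(object@atoms))
    msg <- c(msg, "one stability score per atom required")
  if (is.null(msg)) TRUE else msg
})

#' @rdname StateDictionary-class
setMethod("atoms", "StateDictionary", function(x) x@atoms)
#' @rdname StateDictionary-class
setMethod("stability", "StateDictionary", function(x) x@stability)
#' @rdname StateDictionary-class
setMethod("orderingTag", "StateDictionary", function(x) x@orderingTag)

setMethod("show", "StateDictionary", function(object) {
  cat(sprintf("StateDictionary: %d atoms x %d edges, %d fold(s)",
              nrow(object@atoms), ncol(object@atoms), object@foldCount))
  if (!anyNA(object@stability))
    cat(sprintf(", stability %.2f-%.2f", min(object@stability),
                max(object@stability)))
  cat("\n")
})

# fix each atom's sign so its largest-|value| entry is positive; rows of A
# (codes) are flipped along
applySignConvention <- function(D, A = NULL) {
  for (k in seq_len(nrow(D))) {
    j <- which.max(abs(D[k, ]))
    if (D[k, j] < 0) {
      D[k, ] <- -D[k, ]
      if (!is.null(A)) A[k, ] <- -A[k, ]
    }
  }
  list(D = D, A = A)
}

softThreshold <- function(x, lam) sign(x) * pmax(abs(x) - lam, 0)

#' Learn one dictionary fold by sparse coding
#'
#' Alternating minimisation of
#' `0.5 * ||X - D'A||_F^2 + lambda * sum(|A|)` over unit-energy atoms D and
#' sparse codes A: exact coordinate-descent l1 sparse coding given D, then a
#' block coordinate dictionary update (each atom solved in closed form and
#' projected onto the unit l2 ball), so the objective is non-increasing
#' across iterations. Atoms are rescaled to exactly unit norm on exit (codes
#' absorb the scale; the fit D'A is unchanged), signed so each atom's
#' largest-magnitude entry is positive, and ordered by decreasing usage.
#'
#' An atom that ends an iteration unused is re-seeded from the
#' worst-reconstructed window (count in attribute `"n_reseeded"` of the
#' atoms).
#'
#' @param stack pooled window rows (W x E matrix from [poolStacks()]) or a
#'   [WindowStack-class].
#' @param K number of atoms (default 20).
#' @param nIter iterations (default 200).
#' @param lambda l1 penalty; default `0.1 * mean(|D_init X|)`.
#' @param seed RNG seed (atom initialisation from random windows).
#' @param nSweeps coordinate-descent sweeps per sparse-coding step.
#' @param init optional K x E initial dictionary (rows are renormalised);
#'   default initialises from K random windows.
#' @param recordObjective evaluate and store the objective after every
#'   iteration (costs an extra gram/product per iteration; default FALSE).
#' @return a [StateDictionary-class] with `foldCount = 1`; slot `objective`
#'   holds the per-iteration objective when recorded.
#' @export
learnDictionary <- function(stack, K = 20L, nIter = 200L, lambda = NULL,
                            seed = 1L, nSweeps = 3L, init = NULL,
                            recordObjective = FALSE) {
  Xr <- if (is(stack, "WindowStack")) stackMatrix(stack) else stack
  N <- nrow(Xr); E <- ncol(Xr)
  if (N < K) stop("need at least K window rows to learn K atoms")
  if (nIter < 1L) stop("nIter must be >= 1")
  X <- t(Xr)                      # E x N, columns are windows
  if (is.null(init)) {
    D <- withSeed(seed, {
      ini <- Xr[sample.int(N, K), , drop = FALSE]
      nrm <- sqrt(rowSums(ini^2))
      nrm[nrm == 0] <- 1
      ini / nrm
    })
  } else {
    stopifnot(nrow(init) == K, ncol(init) == E)
    nrm <- sqrt(rowSums(init^2)); nrm[nrm == 0] <- 1
    D <- init / nrm
  }
  if (is.null(lambda)) lambda <- 0.1 * mean(abs(D %*% X))
  A <- matrix(0, K, N)
  xn2 <- sum(X^2)
  objective <- if (recordObjective) numeric(nIter) else numeric(0)
  nReseeded <- 0L
  for (it in seq_len(nIter)) {
    G <- tcrossprod(D)            # K x K gram of atoms
    B <- D %*% X                  # K x N
    for (s in seq_len(nSweeps)) {
      for (k in seq_len(K)) {
        r <- B[k, ] - G[k, ] %*% A + G[k, k] * A[k, ]
        A[k, ] <- softThreshold(r, lambda) / G[k, k]
      }
    }
    # dictionary update: block coordinate, unit-ball constrained
    Cm <- tcrossprod(A)
    Em <- X %*% t(A)              # E x K
    for (k in seq_len(K)) {
      if (Cm[k, k] < 1e-12) {     # unused atom: reseed from worst window
        resid <- colSums((X - crossprod(D, A))^2)
        d <- X[, which.max(resid)]
        D[k, ] <- d / sqrt(sum(d^2))
        nReseeded <- nReseeded + 1L
      } else {
        u <- D[k, ] + (Em[, k] - crossprod(D, Cm[, k])) / Cm[k, k]
        D[k, ] <- u / max(1, sqrt(sum(u^2)))
      }
    }
    if (recordObjective) {
      G <- tcrossprod(D)
      B <- D %*% X
      objective[it] <- 0.5 * (xn2 - 2 * sum(B * A) + sum((G %*% A) * A)) +
        lambda * sum(abs(A))
    }
  }
  nrm <- sqrt(rowSums(D^2))
  nrm[nrm == 0] <- 1
  D <- D / nrm
  A <- A * nrm
  sc <- applySignConvention(D, A)
  D <- sc$D; A <- sc$A
  ord <- order(-rowSums(abs(A)), seq_len(K))
  D <- D[ord, , drop = FALSE]
  colnames(D) <- colnames(Xr)
  out <- new("StateDictionary", atoms = D, foldCount = 1L,
             stability = rep(NA_real_, K), orderingTag = "",
             objective = objective, lambda = lambda)
  attr(out@atoms, "n_reseeded") <- nReseeded
  out
}

# Solve the square assignment problem (cost minimisation) by the
# shortest-augmenting-path Hungarian algorithm, O(n^3).
hungarianSolve <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n)        # row potentials
  v <- numeric(n + 1L)   # column potentials, index j+1 (col 0 virtual)
  p <- integer(n + 1L)   # p[j+1]: row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    way <- integer(n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0L:n) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1L]] <- j
  assignment
}

#' Match atoms between two dictionaries (Hungarian assignment)
#'
#' Finds the one-to-one pairing of atoms maximising the total absolute
#' Pearson correlation (spatial correlation over the edge set) between
#' matched pairs, and the sign flip that makes each matched correlation
#' positive.
#'
#' @param dictA,dictB [StateDictionary-class] objects with equal K and edge
#'   sets (matrices of atoms are also accepted).
#' @return list with `permutation` (atom of B matched to each atom of A),
#'   `signs` (+1/-1 per pair), `scores` (matched |correlation|) and
#'   `total` (sum of scores).
#' @export
matchAtoms <- function(dictA, dictB) {
  A <- if (is(dictA, "StateDictionary")) atoms(dictA) else dictA
  B <- if (is(dictB, "StateDictionary")) atoms(dictB) else dictB
  if (!all(dim(A) == dim(B))) stop("dictionaries must share K and edge count")
  S <- suppressWarnings(cor(t(A), t(B)))
  S[is.na(S)] <- 0
  perm <- hungarianSolve(-abs(S))
  matched <- S[cbind(seq_len(nrow(A)), perm)]
  list(permutation = perm,
       signs = ifelse(matched < 0, -1, 1),
       scores = abs(matched),
       total = sum(abs(matched)))
}

#' Consensus dictionary across folds
#'
#' Matches every fold's atoms to the first fold ([matchAtoms()]), applies
#' the permutation and sign flips, averages the aligned atoms and
#' renormalises to unit energy. Per-atom stability is the mean matched
#' |correlation| over folds 2..F (1 when only one fold is supplied).
#'
#' @param folds list of [StateDictionary-class] (>= 1).
#' @param tag ordering tag stamped on the result (default
#'   `"consensus"`); dictionaries must share a tag for their weights to be
#'   compared.
#' @return a [StateDictionary-class].
#' @export
consensusDictionary <- function(folds, tag = "consensus") {
  stopifnot(length(folds) >= 1L)
  ref <- atoms(folds[[1L]])
  K <- nrow(ref)
  acc <- ref
  scores <- matrix(NA_real_, K, length(folds) - 1L)
  if (length(folds) > 1L) {
    for (f in 2L:length(folds)) {
      m <- matchAtoms(folds[[1L]], folds[[f]])
      aligned <- atoms(folds[[f]])[m$permutation, , drop = FALSE] * m$signs
      acc <- acc + aligned
      scores[, f - 1L] <- m$scores
    }
  }
  D <- acc / length(folds)
  nrm <- sqrt(rowSums(D^2))
  nrm[nrm == 0] <- 1
  D <- D / nrm
  D <- applySignConvention(D)$D
  colnames(D) <- colnames(ref)
  stab <- if (ncol(scores) > 0L) rowMeans(scores) else rep(1, K)
  new("StateDictionary", atoms = D, foldCount = length(folds),
      stability = stab, orderingTag = tag,
      objective = numeric(0), lambda = folds[[1L]]@lambda)
}

#' Learn a robust consensus dictionary over many folds
#'
#' Runs [learnDictionary()] `folds` times (fold f seeded with
#' `seed + f`), then merges the folds with [consensusDictionary()]. This is
#' the robust estimation protocol: repeated dictionary learning with
#' Hungarian matching of atoms to the first fold and averaging.
#'
#' @inheritParams learnDictionary
#' @param folds number of folds (default 30).
#' @param tag ordering tag for the consensus (default stamps seed and K).
#' @return a [StateDictionary-class] with `foldCount = folds`.
#' @export
learnConsensusDictionary <- function(stack, K = 20L, folds = 30L,
                                     nIter = 200L, lambda = NULL, seed = 1L,
                                     nSweeps = 3L, tag = NULL) {
  if (is.null(tag)) tag <- sprintf("consensus-seed%d-K%d", seed, K)
  fits <- lapply(seq_len(folds), function(f)
    learnDictionary(stack, K = K, nIter = nIter, lambda = lambda,
                    seed = seed + f, nSweeps = nSweeps))
  consensusDictionary(fits, tag = tag)
}

#' Re-fold an atom into its region x region matrix
#'
#' @param dictionary a [StateDictionary-class].
#' @param k atom index.
#' @param labels optional region labels.
#' @return symmetric R x R matrix (zero diagonal) of the atom's edge values.
#' @export
atomMatrix <- function(dictionary, k, labels = NULL) {
  unvecUpperTri(atoms(dictionary)[k, ], diag = 0, labels = labels)
}

#' Cosine similarity between two sets of atoms
#'
#' @param A,B K1 x E and K2 x E matrices.
#' @return K1 x K2 matrix of cosine similarities (rows normalised; a zero
#'   row yields 0).
#' @export
cosineSimilarity <- function(A, B) {
  normRows <- function(m) {
    nrm <- sqrt(rowSums(m^2))
    nrm[nrm == 0] <- Inf
    m / nrm
  }
  tcrossprod(normRows(A), normRows(B))
}

#' Convert a state correlation matrix to a unit-energy atom vector
#'
#' Vectorizes the upper triangle of a planted state pattern, optionally
#' Fisher z-transforms it (to live on the same scale as a z-scale window
#' stack), and normalises to unit l2 norm -- making planted states directly
#' comparable to learned atoms.
#'
#' @param pattern R x R correlation matrix.
#' @param scale `"z"` (default, matches z-scale stacks) or `"r"`.
#' @return unit-norm numeric vector of length R(R-1)/2.
#' @export
patternToAtomVector <- function(pattern, scale = "z") {
  v <- vecUpperTri(pattern)
  if (scale == "z") {
    v <- fisherZValues(v)
    attr(v, "n_clipped") <- NULL
  }
  v / sqrt(sum(v^2))
}

#' Match learned atoms to planted ground-truth states
#'
#' For each planted state pattern, finds the dictionary atom with the
#' highest |cosine| similarity to the state's (z-scale) edge vector --
#' the recovery yardstick for simulation studies.
#'
#' @param dictionary a [StateDictionary-class] (or K x E atom matrix).
#' @param patterns list of R x R state correlation matrices (e.g.
#'   `truth$statePatterns` of a simulated cohort).
#' @param scale scale of the dictionary's stack, `"z"` (default) or `"r"`.
#' @return data.frame with one row per planted state: `state`, `atom`
#'   (best-matching atom index), `cosine` (absolute cosine similarity).
#' @export
stateRecovery <- function(dictionary, patterns, scale = "z") {
  D <- if (is(dictionary, "StateDictionary")) atoms(dictionary) else dictionary
  Tm <- do.call(rbind, lapply(patterns, patternToAtomVector, scale = scale))
  S <- abs(cosineSimilarity(Tm, D))
  data.frame(state = seq_along(patterns),
             atom = apply(S, 1L, which.max),
             cosine = apply(S, 1L, max), row.names = NULL)
}
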