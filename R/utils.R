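#' @import methods
#' @importFrom stats cor sd rnorm rgeom pt pf p.adjust as.dist hclust cov2cor
#'   ks.test runif var aggregate setNames
#' @importFrom utils combn write.table read.table packageVersion write.csv
#'   read.csv head
NULL

# Row-major (i < j) upper-triangle index pairs for an R x R matrix.
upperTriPairs <- function(R) {
  if (R < 2) stop("need at least 2 regions for an edge set")
  t(combn(R, 2L))
}

# Linear indices into an R x R matrix for the row-major upper triangle.
upperTriIndex <- function(R) {
  p <- upperTriPairs(R)
  (p[, 2L] - 1L) * R + p[, 1L]
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Entries are taken row-major over pairs (i, j) with i < j, i.e.
#' (1,2), (1,3), ..., (1,R), (2,3), ...
#'
#' @param m symmetric numeric matrix.
#' @return numeric vector of length `R(R-1)/2`, named `"a--b"` from the
#'   matrix dimnames when present.
#' @seealso [unvecUpperTri()]
#' @export
vecUpperTri <- function(m) {
  R <- nrow(m)
  v <- m[upperTriIndex(R)]
  if (!is.null(rownames(m))) {
    p <- upperTriPairs(R)
    names(v) <- paste(rownames(m)[p[, 1L]], rownames(m)[p[, 2L]], sep = "--")
  }
  v
}

#' Rebuild a symmetric matrix from an upper-triangle vector
#'
#' @param v vector as produced by [vecUpperTri()].
#' @param diag value placed on the diagonal (default 1).
#' @param labels optional region labels for dimnames.
#' @return symmetric R x R matrix.
#' @export
unvecUpperTri <- function(v, diag = 1, labels = NULL) {
  E <- length(v)
  R <- (1 + sqrt(1 + 8 * E)) / 2
  if (abs(R - round(R)) > 1e-9) stop("length is not R(R-1)/2 for integer R")
  R <- as.integer(round(R))
  m <- matrix(0, R, R)
  m[upperTriIndex(R)] <- v
  m <- m + t(m)
  base::diag(m) <- diag
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  m
}

# Evaluate expr with a temporary RNG state seeded at `seed`; the caller's
# RNG stream is untouched.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Deterministic per-subject sub-seed derived from a master seed; kept
# inside 32-bit integer range.
subSeed <- function(master, doseIndex, subjectIndex) {
  as.integer((as.double(master) * 7919 + doseIndex * 1299709 +
                subjectIndex * 104729) %% 2147483647L)
}

# Project a symmetric matrix to the nearest PSD matrix by eigenvalue
# clipping; returns the matrix with attribute "psd_distance" (Frobenius
# distance moved, 0 when already PSD within tol).
nearestPSD <- function(m, tol = 1e-8) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= -tol) {
    attr(m, "psd_distance") <- 0
    return(m)
  }
  lam <- pmax(e$values, 0)
  out <- e$vectors %*% (lam * t(e$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(m)
  attr(out, "psd_distance") <- sqrt(sum((out - m)^2))
  out
}

# Fisher z-transform with clipping of |r| at 1 - eps; returns vector/matrix
# of atanh values, attribute "n_clipped" counts clipped entries.
fisherZValues <- function(r, eps = 1e-7) {
  clipped <- abs(r) > 1 - eps
  r[clipped] <- sign(r[clipped]) * (1 - eps)
  z <- atanh(r)
  attr(z, "n_clipped") <- sum(clipped)
  z
}
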