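#' Vectorize an FC matrix to its edge vector
#'
#' @param fc an [FCMatrix-class].
#' @return named numeric vector of upper-triangle edges (row-major, i < j).
#' @export
edgeVector <- function(fc) vecUpperTri(fcValues(fc))

# subjects x edges matrix from a list of FCMatrix objects
stackEdges <- function(fcs) {
  do.call(rbind, lapply(fcs, edgeVector))
}

colVars <- function(x) {
  n <- nrow(x)
  colSums(sweep(x, 2L, colMeans(x))^2) / (n - 1)
}

# pooled-variance unpaired t per column of A (nA x E) vs B (nB x E);
# zero pooled variance is floored and flagged
pooledT <- function(A, B) {
  nA <- nrow(A); nB <- nrow(B)
  sp2 <- ((nA - 1) * colVars(A) + (nB - 1) * colVars(B)) / (nA + nB - 2)
  flagged <- sp2 == 0
  sp2[flagged] <- .Machine$double.eps
  t <- (colMeans(A) - colMeans(B)) / sqrt(sp2 * (1 / nA + 1 / nB))
  structure(t, flagged = flagged)
}

#' Edge-wise two-group test with max-statistic permutation correction
#'
#' Computes an unpaired pooled-variance t statistic per edge, then corrects
#' for the full edge family by permuting the subject ordering: each
#' permutation relabels subjects across the two groups and records the
#' maximum |t| over all edges; the corrected p of an edge is the fraction of
#' the null (plus the observed labelling) whose maximum reaches its |t|.
#' Uncorrected two-sided t p-values and their Benjamini-Hochberg q-values are
#' reported alongside.
#'
#' @param groupA,groupB subjects x edges matrices with matching columns.
#' @param nPerm number of random permutations (default 5000).
#' @param seed RNG seed for the permutations.
#' @param exact enumerate all label assignments instead of sampling
#'   (feasible for small groups); `nPerm` is then ignored and the corrected
#'   p is the exact proportion over all relabelings (identity included).
#' @param covariates optional (nA+nB) x p numeric matrix of nuisance
#'   covariates (rows ordered group A then group B, e.g. heart rate); each
#'   edge is residualised on the covariates (with intercept) before testing.
#' @return data.frame with columns `edge`, `t`, `p_uncorrected`, `p_maxT`,
#'   `q_fdr`; attributes `nPerm`, `maxT_null` (the null maxima) and
#'   `flagged` (edges whose pooled variance was floored).
#' @export
edgeGroupTest <- function(groupA, groupB, nPerm = 5000L, seed = 1L,
                          exact = FALSE, covariates = NULL) {
  if (ncol(groupA) != ncol(groupB)) stop("edge sets differ between groups")
  nA <- nrow(groupA); nB <- nrow(groupB)
  if (nA < 2L || nB < 2L) stop("need at least 2 subjects per group")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != nA + nB)
      stop("covariates must have one row per subject (group A then group B)")
    Z <- cbind(1, covariates)
    both <- rbind(groupA, groupB)
    res <- both - Z %*% qr.coef(qr(Z), both)
    groupA <- res[seq_len(nA), , drop = FALSE]
    groupB <- res[nA + seq_len(nB), , drop = FALSE]
  }
  if (!exact && nPerm < 100L)
    warning("fewer than 100 permutations gives a very coarse corrected p")
  tObs <- pooledT(groupA, groupB)
  flagged <- attr(tObs, "flagged")
  X <- rbind(groupA, groupB)
  n <- nA + nB
  df <- n - 2L
  if (exact) {
    sel <- combn(n, nA)
    maxT <- apply(sel, 2L, function(idx)
      max(abs(pooledT(X[idx, , drop = FALSE], X[-idx, , drop = FALSE]))))
    pCorr <- vapply(abs(tObs), function(t0) mean(maxT >= t0 - 1e-12), numeric(1))
    nPermUsed <- ncol(sel)
  } else {
    maxT <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
      idx <- sample.int(n, nA)
      max(abs(pooledT(X[idx, , drop = FALSE], X[-idx, , drop = FALSE])))
    }, numeric(1)))
    pCorr <- vapply(abs(tObs), function(t0)
      (1 + sum(maxT >= t0 - 1e-12)) / (1 + nPerm), numeric(1))
    nPermUsed <- nPerm
  }
  pUnc <- 2 * pt(abs(tObs), df = df, lower.tail = FALSE)
  out <- data.frame(edge = colnames(groupA) %||% seq_along(tObs),
                    t = as.numeric(tObs), p_uncorrected = pUnc,
                    p_maxT = pCorr,
                    q_fdr = p.adjust(pUnc, method = "BH"),
                    row.names = NULL)
  attr(out, "nPerm") <- nPermUsed
  attr(out, "maxT_null") <- maxT
  attr(out, "flagged") <- flagged
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' One-way ANOVA for a dose effect at every edge
#'
#' Standard one-way fixed-effects ANOVA per edge across the dose groups (the
#' null hypothesis being no effect of anesthetic dose on that edge), with
#' Benjamini-Hochberg correction across edges. With two groups the F
#' statistic equals the square of the unpaired equal-variance t.
#'
#' @param groups named list of subjects x edges matrices, one per dose.
#' @return data.frame with columns `edge`, `F`, `p`, `q_fdr`; attribute
#'   `df = c(between, within)`.
#' @export
anovaDoseEffect <- function(groups) {
  if (length(groups) < 2L) stop("need at least 2 dose groups")
  ns <- vapply(groups, nrow, integer(1))
  if (any(ns < 2L)) stop("need at least 2 subjects in every group")
  E <- ncol(groups[[1L]])
  if (!all(vapply(groups, ncol, integer(1)) == E)) stop("edge sets differ")
  N <- sum(ns); G <- length(groups)
  means <- do.call(rbind, lapply(groups, colMeans))   # G x E
  vars <- do.call(rbind, lapply(groups, colVars))
  grand <- colSums(means * ns) / N
  ssb <- colSums(ns * sweep(means, 2L, grand)^2)
  ssw <- colSums((ns - 1) * vars)
  dfB <- G - 1L; dfW <- N - G
  Fst <- (ssb / dfB) / (ssw / dfW)
  p <- pf(Fst, dfB, dfW, lower.tail = FALSE)
  out <- data.frame(edge = colnames(groups[[1L]]) %||% seq_len(E),
                    F = Fst, p = p, q_fdr = p.adjust(p, method = "BH"),
                    row.names = NULL)
  attr(out, "df") <- c(between = dfB, within = dfW)
  out
}

#' Benjamini-Hochberg FDR step-up
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` returning both the
#' q-values and the rejection mask at level `alpha`.
#'
#' @param p p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `q` (BH-adjusted p-values) and `reject` (logical).
#' @export
bhFdr <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  q <- p.adjust(p, method = "BH")
  list(q = q, reject = q <= alpha)
}

#' Hierarchical clustering of network nodes
#'
#' Average-linkage agglomerative clustering of the regions of an FC matrix
#' under the distance `1 - |correlation|`, the dendrogram view of the
#' network's modular structure.
#'
#' @param fc an [FCMatrix-class].
#' @return an [stats::hclust] object.
#' @export
clusterEdges <- function(fc) {
  v <- fcValues(fc)
  d <- 1 - abs(v)
  diag(d) <- 0
  hclust(as.dist(d), method = "average")
}

#' Export a dendrogram as a Newick string
#'
#' @param h an [stats::hclust] object (e.g. from [clusterEdges()]).
#' @return single Newick-format string with branch lengths.
#' @export
dendrogramNewick <- function(h) {
  ape::write.tree(ape::as.phylo(h))
}
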