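#' WeightTimeSeries: back-fitted atom weights of one subject
#'
#' The windows x K matrix of least-squares weights of each dictionary atom
#' in each sliding window, plus the per-atom scalar summary used for group
#' statistics: the mean absolute weight over windows (the mean absolute sum
#' of the state's fluctuations).
#'
#' @slot weights W x K numeric matrix.
#' @slot summary length-K numeric, `colMeans(|weights|)`.
#' @slot subject source subject id.
#' @slot orderingTag tag of the dictionary the weights were fitted against.
#'
#' @aliases weightMatrix weightSummary
#' @export
setClass("WeightTimeSeries",
  representation(weights = "matrix", summary = "numeric",
                 subject = "character", orderingTag = "character"))

setValidity("WeightTimeSeries", function(object) {
  msg <- NULL
  if (length(object@summary) != ncol(object@weights))
    msg <- c(msg, "one summary value per atom required")
  if (any(object@summary < 0)) msg <- c(msg, "summaries must be nonnegative")
  if (is.null(msg)) TRUE else msg
})

#' @rdname WeightTimeSeries-class
setMethod("weightMatrix", "WeightTimeSeries", function(x) x@weights)
#' @rdname WeightTimeSeries-class
setMethod("weightSummary", "WeightTimeSeries", function(x) x@summary)
#' @rdname WeightTimeSeries-class
setMethod("subjectId", "WeightTimeSeries", function(x) x@subject)
#' @rdname WeightTimeSeries-class
setMethod("orderingTag", "WeightTimeSeries", function(x) x@orderingTag)

setMethod("show", "WeightTimeSeries", function(object) {
  cat(sprintf("WeightTimeSeries '%s': %d windows x %d atoms\n",
              object@subject, nrow(object@weights), ncol(object@weights)))
})

#' Back-fit atom weights by least squares
#'
#' Projects every window of the stack onto the dictionary atoms by
#' unpenalised least squares (`A = (DD')^{-1} D x` per window): the
#' least-squares projection back-fitting of the learned states onto each
#' subject's windowed connectivity.
#'
#' @param dictionary a [StateDictionary-class].
#' @param stack a [WindowStack-class] or W x E matrix sharing the
#'   dictionary's edge set.
#' @return a [WeightTimeSeries-class].
#' @export
backfitWeights <- function(dictionary, stack) {
  D <- atoms(dictionary)
  Xr <- if (is(stack, "WindowStack")) stackMatrix(stack) else stack
  subject <- if (is(stack, "WindowStack")) subjectId(stack) else "matrix"
  if (ncol(D) != ncol(Xr))
    stop("dictionary and stack edge sets differ (", ncol(D), " vs ", ncol(Xr), ")")
  G <- tcrossprod(D)
  if (rcond(G) < 1e-12)
    stop("rank-deficient dictionary; condition number ",
         format(kappa(G, exact = TRUE), digits = 4))
  A <- solve(G, D %*% t(Xr))            # K x W
  W <- t(A)
  colnames(W) <- paste0("atom", seq_len(nrow(D)))
  new("WeightTimeSeries", weights = W, summary = colMeans(abs(W)),
      subject = subject, orderingTag = dictionary@orderingTag)
}

#' Fraction of window-stack variance explained by a dictionary
#'
#' `1 - ||X - D'A||_F^2 / ||X - mean(X)||_F^2` with back-fitted
#' least-squares weights A. A negative value (dictionary span worse than the
#' grand mean) is reported as 0 with attribute `"clamped" = TRUE`.
#'
#' @inheritParams backfitWeights
#' @return scalar in `[0, 1]`.
#' @export
varianceExplained <- function(dictionary, stack) {
  Xr <- if (is(stack, "WindowStack")) stackMatrix(stack) else stack
  ssTot <- sum((Xr - mean(Xr))^2)
  if (ssTot == 0) stop("constant window stack: variance explained undefined")
  wt <- backfitWeights(dictionary, stack)
  fit <- weightMatrix(wt) %*% atoms(dictionary)
  ve <- 1 - sum((Xr - fit)^2) / ssTot
  if (ve < 0) structure(0, clamped = TRUE) else ve
}

#' Stack per-subject weight summaries into a group matrix
#'
#' @param weightList list of [WeightTimeSeries-class] fitted against the
#'   same (identically tagged) dictionary.
#' @return subjects x K matrix of mean absolute weights.
#' @export
summaryMatrix <- function(weightList) {
  tags <- unique(vapply(weightList, orderingTag, character(1)))
  if (length(tags) > 1L)
    stop("weights were fitted against differently ordered dictionaries: ",
         paste(tags, collapse = " vs "))
  out <- do.call(rbind, lapply(weightList, weightSummary))
  rownames(out) <- vapply(weightList, subjectId, character(1))
  out
}

#' Rank atoms by group-mean summary weight
#'
#' @param summaries subjects x K matrix (or list of
#'   [WeightTimeSeries-class]).
#' @return atom indices in decreasing order of mean summary (ties broken by
#'   atom index).
#' @export
rankStates <- function(summaries) {
  if (is.list(summaries)) summaries <- summaryMatrix(summaries)
  if (is.null(dim(summaries))) summaries <- matrix(summaries, nrow = 1L)
  m <- colMeans(summaries)
  order(-m, seq_along(m))
}

#' Compare state weights between two groups
#'
#' Per-atom unpaired pooled-variance t-test on the scalar summaries (mean
#' absolute weight), with Benjamini-Hochberg correction across the K atoms.
#' Requires the two groups' weights to come from identically ordered
#' dictionaries (matching ordering tags) so atom k means the same state in
#' both groups.
#'
#' @param groupA,groupB subjects x K summary matrices (or lists of
#'   [WeightTimeSeries-class]).
#' @return data.frame with columns `atom`, `meanA`, `meanB`, `t`, `p`,
#'   `q_fdr`.
#' @export
compareWeights <- function(groupA, groupB) {
  tagOf <- function(g) if (is.list(g))
    unique(vapply(g, orderingTag, character(1))) else NULL
  ta <- tagOf(groupA); tb <- tagOf(groupB)
  if (!is.null(ta) && !is.null(tb) && !identical(ta, tb))
    stop("ordering tags differ between groups: ", ta, " vs ", tb)
  if (is.list(groupA)) groupA <- summaryMatrix(groupA)
  if (is.list(groupB)) groupB <- summaryMatrix(groupB)
  if (ncol(groupA) != ncol(groupB)) stop("atom counts differ between groups")
  if (nrow(groupA) < 2L || nrow(groupB) < 2L)
    stop("need at least 2 subjects per group")
  t <- pooledT(groupA, groupB)
  df <- nrow(groupA) + nrow(groupB) - 2L
  p <- 2 * pt(abs(t), df = df, lower.tail = FALSE)
  data.frame(atom = seq_len(ncol(groupA)), meanA = colMeans(groupA),
             meanB = colMeans(groupB), t = as.numeric(t), p = p,
             q_fdr = p.adjust(p, method = "BH"), row.names = NULL)
}
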