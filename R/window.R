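#' WindowStack: sliding-window connectivity of one subject
#'
#' Each row is the vectorized upper triangle (row-major, i < j) of the
#' Pearson correlation matrix of one window of the subject's time series,
#' optionally Fisher z-transformed. With step 1 there are
#' `T - windowLength + 1` windows.
#'
#' @slot values W x E matrix (E = R(R-1)/2), columns named by edge.
#' @slot windowLength window length in timepoints.
#' @slot step window step in timepoints.
#' @slot subject source subject id.
#' @slot scale `"r"` or `"z"`.
#'
#' @aliases stackMatrix edgeNames
#' @export
setClass("WindowStack",
  representation(values = "matrix", windowLength = "integer", step = "integer",
                 subject = "character", scale = "character"))

setValidity("WindowStack", function(object) {
  msg <- NULL
  if (object@windowLength < 2L) msg <- c(msg, "windowLength must be >= 2")
  if (object@step < 1L) msg <- c(msg, "step must be >= 1")
  if (!object@scale %in% c("r", "z")) msg <- c(msg, "scale must be 'r' or 'z'")
  if (object@scale == "r" && nrow(object@values) > 0 &&
      max(abs(object@values)) > 1 + 1e-10)
    msg <- c(msg, "r-scale window correlations must lie in [-1, 1]")
  if (is.null(msg)) TRUE else msg
})

#' @rdname WindowStack-class
setMethod("stackMatrix", "WindowStack", function(x) x@values)
#' @rdname WindowStack-class
setMethod("edgeNames", "WindowStack", function(x) colnames(x@values))
#' @rdname WindowStack-class
setMethod("subjectId", "WindowStack", function(x) x@subject)

setMethod("show", "WindowStack", function(object) {
  cat(sprintf("WindowStack '%s': %d windows x %d edges (window %d, step %d, %s scale)\n",
              object@subject, nrow(object@values), ncol(object@values),
              object@windowLength, object@step, object@scale))
})

#' Sliding-window functional connectivity
#'
#' Slides a rectangular window of `windowLength` timepoints across the
#' series in increments of `step` and computes the full Pearson correlation
#' of each (demeaned) window segment. A region with zero variance inside a
#' window gets zero correlation on its edges for that window (counted in the
#' `"n_degenerate"` attribute).
#'
#' @param ts a [SubjectTimeSeries-class] or T x R matrix.
#' @param windowLength window length in timepoints (default 40, i.e. 40 TR).
#' @param step step increment in timepoints (default 1 TR).
#' @param applyFisherZ transform window correlations with `atanh`
#'   (default TRUE).
#' @return a [WindowStack-class].
#' @export
slidingWindowFC <- function(ts, windowLength = 40L, step = 1L,
                            applyFisherZ = TRUE) {
  Y <- if (is(ts, "SubjectTimeSeries")) seriesMatrix(ts) else ts
  subject <- if (is(ts, "SubjectTimeSeries")) subjectId(ts) else "matrix"
  T <- nrow(Y); R <- ncol(Y)
  windowLength <- as.integer(windowLength); step <- as.integer(step)
  if (windowLength > T) stop("windowLength exceeds the series length")
  starts <- seq.int(1L, T - windowLength + 1L, by = step)
  idx <- upperTriIndex(R)
  pairs <- upperTriPairs(R)
  lab <- colnames(Y) %||% paste0("r", seq_len(R))
  edgeLab <- paste(lab[pairs[, 1L]], lab[pairs[, 2L]], sep = "--")
  nDegenerate <- 0L
  rows <- matrix(0, length(starts), length(idx))
  for (w in seq_along(starts)) {
    seg <- Y[starts[w]:(starts[w] + windowLength - 1L), , drop = FALSE]
    cm <- suppressWarnings(cor(seg))
    if (anyNA(cm)) {          # zero-variance region inside this window
      nDegenerate <- nDegenerate + sum(apply(seg, 2L, sd) == 0)
      cm[is.na(cm)] <- 0
    }
    rows[w, ] <- cm[idx]
  }
  colnames(rows) <- edgeLab
  scale <- "r"
  if (applyFisherZ) {
    rows <- fisherZValues(rows)
    attr(rows, "n_clipped") <- NULL
    colnames(rows) <- edgeLab
    scale <- "z"
  }
  out <- new("WindowStack", values = rows, windowLength = windowLength,
             step = step, subject = subject, scale = scale)
  attr(out@values, "n_degenerate") <- nDegenerate
  out
}

#' Pool window stacks across subjects
#'
#' Row-binds the window matrices of several subjects (the concatenated input
#' dictionary learning is run on). Stacks must agree in edge set, window
#' length, step and scale.
#'
#' @param stacks list of [WindowStack-class].
#' @return W_total x E matrix with attribute `"subject"` giving the source
#'   subject of each row.
#' @export
poolStacks <- function(stacks) {
  stopifnot(length(stacks) >= 1L)
  e1 <- edgeNames(stacks[[1L]])
  ok <- vapply(stacks, function(s)
    identical(edgeNames(s), e1) &&
      s@windowLength == stacks[[1L]]@windowLength &&
      s@step == stacks[[1L]]@step && s@scale == stacks[[1L]]@scale,
    logical(1))
  if (!all(ok)) stop("window stacks are not compatible")
  out <- do.call(rbind, lapply(stacks, stackMatrix))
  attr(out, "subject") <- rep(vapply(stacks, subjectId, character(1)),
                              vapply(stacks, function(s) nrow(stackMatrix(s)),
                                     integer(1)))
  attr(out, "n_degenerate") <- NULL
  out
}
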