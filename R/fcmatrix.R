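#' FCMatrix: a region x region functional-connectivity matrix
#'
#' Symmetric matrix of full or partial correlations between regional time
#' courses, on the raw correlation (`r`) or Fisher-z (`z`) scale.
#'
#' @slot values symmetric R x R numeric matrix with region dimnames.
#' @slot kind `"full"` or `"partial"`.
#' @slot scale `"r"` or `"z"`.
#'
#' @aliases fcValues fcKind fcScale
#' @export
setClass("FCMatrix",
  representation(values = "matrix", kind = "character", scale = "character"))

setValidity("FCMatrix", function(object) {
  msg <- NULL
  v <- object@values
  if (nrow(v) != ncol(v) || max(abs(v - t(v))) > 1e-10)
    msg <- c(msg, "values must be symmetric within 1e-10")
  if (!object@kind %in% c("full", "partial")) msg <- c(msg, "kind must be 'full' or 'partial'")
  if (!object@scale %in% c("r", "z")) msg <- c(msg, "scale must be 'r' or 'z'")
  if (object@scale == "r" && max(abs(diag(v) - 1)) > 1e-8)
    msg <- c(msg, "unit diagonal required on the r scale")
  if (is.null(colnames(v))) msg <- c(msg, "region labels required as dimnames")
  if (is.null(msg)) TRUE else msg
})

#' @rdname FCMatrix-class
setMethod("fcValues", "FCMatrix", function(x) x@values)
#' @rdname FCMatrix-class
setMethod("fcKind", "FCMatrix", function(x) x@kind)
#' @rdname FCMatrix-class
setMethod("fcScale", "FCMatrix", function(x) x@scale)
#' @rdname FCMatrix-class
setMethod("regionLabels", "FCMatrix", function(x) colnames(x@values))

setMethod("show", "FCMatrix", function(object) {
  cat(sprintf("FCMatrix: %d x %d %s correlation (%s scale)\n",
              nrow(object@values), ncol(object@values), object@kind,
              object@scale))
})

#' Full (Pearson) correlation network
#'
#' @param ts a [SubjectTimeSeries-class] (or plain T x R matrix with region
#'   column names).
#' @return an [FCMatrix-class] (`kind = "full"`, `scale = "r"`).
#' @export
fullCorrelation <- function(ts) {
  Y <- if (is(ts, "SubjectTimeSeries")) seriesMatrix(ts) else ts
  if (nrow(Y) < 3L) stop("need at least 3 timepoints for a correlation network")
  s <- apply(Y, 2L, sd)
  if (any(s == 0))
    stop("zero-variance region(s): ", paste(colnames(Y)[s == 0], collapse = ", "))
  m <- cor(Y)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  new("FCMatrix", values = m, kind = "full", scale = "r")
}

#' Partial correlation network from a ridge-regularised precision matrix
#'
#' Inverts the (optionally ridge-regularised) sample correlation matrix and
#' converts the precision Theta to partial correlations,
#' `p_ij = -Theta_ij / sqrt(Theta_ii * Theta_jj)` -- the correlation between
#' each region pair after regressing out all other regions. The ridge
#' (`ridgeRho`, on the correlation scale) keeps the inversion stable when
#' timepoints are scarce relative to regions.
#'
#' @param ts a [SubjectTimeSeries-class] or T x R matrix.
#' @param ridgeRho ridge added to the diagonal of the correlation matrix
#'   before inversion (default 0.1).
#' @return an [FCMatrix-class] (`kind = "partial"`, `scale = "r"`).
#' @export
partialCorrelation <- function(ts, ridgeRho = 0.1) {
  Y <- if (is(ts, "SubjectTimeSeries")) seriesMatrix(ts) else ts
  R <- ncol(Y)
  if (nrow(Y) <= R && ridgeRho <= 0)
    stop("T <= R with no ridge: covariance is singular, set ridgeRho > 0")
  C <- cor(Y)
  Creg <- C + diag(ridgeRho, R)
  theta <- tryCatch(solve(Creg), error = function(e)
    stop("correlation matrix is singular; increase ridgeRho (",
         conditionMessage(e), ")"))
  p <- -theta / sqrt(diag(theta) %o% diag(theta))
  diag(p) <- 1
  p <- (p + t(p)) / 2
  dimnames(p) <- dimnames(C)
  new("FCMatrix", values = p, kind = "partial", scale = "r")
}

#' Fisher z-transform of an FC matrix
#'
#' Applies `atanh` elementwise (variance-stabilising for correlations).
#' Off-diagonal entries with |r| at or above 1 are clipped to
#' `1 - 1e-7`; the number of clipped entries is kept as attribute
#' `"n_clipped"` on the values.
#'
#' @param fc an [FCMatrix-class] on the `r` scale.
#' @return an [FCMatrix-class] on the `z` scale (diagonal set to 0).
#' @export
fisherZ <- function(fc) {
  stopifnot(is(fc, "FCMatrix"))
  if (fc@scale == "z") return(fc)
  v <- fc@values
  diag(v) <- 0
  z <- fisherZValues(v)
  nclip <- attr(z, "n_clipped")
  attr(z, "n_clipped") <- NULL
  diag(z) <- 0
  out <- new("FCMatrix", values = z, kind = fc@kind, scale = "z")
  attr(out@values, "n_clipped") <- nclip
  out
}

#' Extract homotopic (left/right mirror pair) edge values
#'
#' @param fc an [FCMatrix-class].
#' @param atlas a [ModuleAtlas-class] whose regions match `fc`.
#' @return named numeric vector, one value per homotopic pair, in atlas
#'   (module) order; names `"left--right"`.
#' @export
homotopicEdges <- function(fc, atlas) {
  v <- fcValues(fc)
  p <- homotopicPairs(atlas)
  if (!all(c(p) %in% colnames(v)))
    stop("atlas regions missing from the FC matrix")
  out <- v[cbind(match(p[, 1L], rownames(v)), match(p[, 2L], colnames(v)))]
  names(out) <- paste(p[, 1L], p[, 2L], sep = "--")
  out
}

#' Reorder an FC matrix to atlas (module) order
#'
#' @param fc an [FCMatrix-class].
#' @param atlas a [ModuleAtlas-class].
#' @return an [FCMatrix-class] with rows/columns in atlas order.
#' @export
orderByAtlas <- function(fc, atlas) {
  v <- fcValues(fc)
  idx <- match(regionLabels(atlas), colnames(v))
  if (anyNA(idx)) stop("FC matrix is missing atlas regions")
  new("FCMatrix", values = v[idx, idx], kind = fc@kind, scale = fc@scale)
}

#' Write an FC matrix as CSV with region-label headers
#'
#' @param fc an [FCMatrix-class].
#' @param path file path.
#' @export
writeFCMatrixCSV <- function(fc, path) {
  write.csv(fcValues(fc), path, row.names = TRUE)
  invisible(path)
}
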