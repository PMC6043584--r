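#' SpatialMapSet: group-level spatial maps
#'
#' A components x voxels matrix of z-scored group spatial maps (e.g. group
#' ICA components), the stage-1 design of dual regression.
#'
#' @slot maps C x V numeric matrix, rownames are component labels.
#' @export
setClass("SpatialMapSet", representation(maps = "matrix"))

setValidity("SpatialMapSet", function(object) {
  m <- object@maps
  msg <- NULL
  if (nrow(m) > ncol(m)) msg <- c(msg, "more components than voxels (C must be <= V)")
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) msg <- c(msg, "every map must have nonzero norm")
  if (is.null(msg)) TRUE else msg
})

#' @rdname SpatialMapSet-class
#' @param maps C x V numeric matrix.
#' @export
spatialMapSet <- function(maps) {
  if (is.null(rownames(maps))) rownames(maps) <- paste0("IC", seq_len(nrow(maps)))
  new("SpatialMapSet", maps = maps)
}

#' High-pass filter time courses (Gaussian-weighted local linear detrending)
#'
#' Removes slow drifts the way FSL's high-pass temporal filter does: at each
#' timepoint a straight line is fitted to the series under Gaussian weights
#' of scale `sigmaS` seconds (`sigmaS / tr` samples), and the fitted local
#' trend is subtracted. Constants and slow ramps are removed almost exactly;
#' oscillations much faster than `sigmaS` pass essentially untouched. Each
#' output column is additionally demeaned.
#'
#' @param ts a [SubjectTimeSeries-class].
#' @param sigmaS Gaussian kernel scale in seconds (default 75, a 150 s
#'   high-pass cutoff at TR = 1 s).
#' @return filtered [SubjectTimeSeries-class].
#' @export
highpassFilter <- function(ts, sigmaS = 75) {
  stopifnot(sigmaS > 0)
  tr <- repetitionTime(ts)
  if (sigmaS <= 2 * tr)
    warning("sigmaS <= 2*TR: the filter degenerates toward simple demeaning")
  Y <- seriesMatrix(ts)
  T <- nrow(Y)
  sd <- sigmaS / tr
  tt <- seq_len(T)
  fitted <- matrix(0, T, ncol(Y))
  for (t in tt) {
    d <- tt - t
    w <- exp(-0.5 * (d / sd)^2)
    S0 <- sum(w); S1 <- sum(w * d); S2 <- sum(w * d^2)
    a <- w %*% Y            # weighted sums per region
    b <- (w * d) %*% Y
    fitted[t, ] <- (S2 * a - S1 * b) / (S0 * S2 - S1^2)
  }
  out <- Y - fitted
  out <- sweep(out, 2L, colMeans(out))
  new("SubjectTimeSeries", values = out, tr = ts@tr, subject = ts@subject,
      dose = ts@dose, group = ts@group)
}

#' Variance-normalise time courses
#'
#' Demeans each region and scales it to unit sample variance.
#'
#' @param ts a [SubjectTimeSeries-class].
#' @return normalised [SubjectTimeSeries-class].
#' @export
varianceNormalize <- function(ts) {
  Y <- seriesMatrix(ts)
  s <- apply(Y, 2L, sd)
  if (any(s == 0))
    stop("zero-variance region(s): ",
         paste(colnames(Y)[s == 0], collapse = ", "))
  out <- scale(Y, center = TRUE, scale = s)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  new("SubjectTimeSeries", values = out, tr = ts@tr, subject = ts@subject,
      dose = ts@dose, group = ts@group)
}

#' Dual regression: group maps -> subject time courses -> subject maps
#'
#' Stage 1 regresses the group spatial maps (plus an intercept) into each
#' volume of the subject's 4-D data, yielding one time course per component;
#' the time courses are variance-normalised. Stage 2 regresses these time
#' courses (plus an intercept) into every voxel's series, yielding
#' subject-specific spatial maps.
#'
#' @param groupMaps a [SpatialMapSet-class] or C x V matrix.
#' @param subjectData T x V matrix (rows are volumes).
#' @param normalize variance-normalise stage-1 time courses (default TRUE).
#' @return list with `timeCourses` (T x C) and `subjectMaps` (C x V).
#' @export
dualRegression <- function(groupMaps, subjectData, normalize = TRUE) {
  M <- if (is(groupMaps, "SpatialMapSet")) groupMaps@maps else groupMaps
  if (ncol(M) != ncol(subjectData))
    stop("voxel count differs between maps (", ncol(M), ") and data (",
         ncol(subjectData), ")")
  C <- nrow(M)
  X1 <- cbind(intercept = 1, t(M))
  q1 <- qr(X1)
  if (q1$rank < ncol(X1))
    stop("group maps are rank deficient (condition number ",
         format(kappa(X1), digits = 4), ")")
  beta1 <- qr.coef(q1, t(subjectData))          # (C+1) x T
  tc <- t(beta1[-1L, , drop = FALSE])           # T x C
  colnames(tc) <- rownames(M)
  if (normalize) {
    s <- apply(tc, 2L, sd)
    if (any(s == 0)) stop("stage-1 time course with zero variance")
    tc <- scale(tc, center = TRUE, scale = s)
    attr(tc, "scaled:center") <- NULL
    attr(tc, "scaled:scale") <- NULL
  }
  X2 <- cbind(intercept = 1, tc)
  beta2 <- qr.coef(qr(X2), subjectData)         # (C+1) x V
  maps <- beta2[-1L, , drop = FALSE]
  rownames(maps) <- rownames(M)
  list(timeCourses = tc, subjectMaps = maps)
}

#' Flatten a 4-D NIfTI volume to a T x V matrix (and back)
#'
#' Thin adapters between NIfTI files and the matrix interfaces of
#' [dualRegression()]: a 4-D image of dimension (x, y, z, T) becomes a
#' T x V matrix with V = x*y*z voxels in array order.
#'
#' @param path NIfTI file path.
#' @return `readNifti4DMatrix`: T x V matrix with attribute `"voldim"`;
#'   `writeNifti4DMatrix` writes `mat` (T x V) as a 4-D image of spatial
#'   dimension `voldim` and returns `path` invisibly.
#' @export
readNifti4DMatrix <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4-D NIfTI image")
  mat <- t(matrix(as.vector(img), prod(d[1:3]), d[4L]))
  attr(mat, "voldim") <- d[1:3]
  mat
}

#' @rdname readNifti4DMatrix
#' @param mat T x V matrix.
#' @param voldim length-3 spatial dimension with `prod(voldim) == V`.
#' @export
writeNifti4DMatrix <- function(mat, voldim, path) {
  stopifnot(prod(voldim) == ncol(mat))
  arr <- array(as.vector(t(mat)), dim = c(voldim, nrow(mat)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}
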