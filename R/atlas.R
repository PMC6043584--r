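#' ModuleAtlas: region-to-network atlas with homotopic pairing
#'
#' Maps each region (an independent-component node of the network) to one of
#' the functional modules of the mouse brain -- by default the lateral
#' cortical (LCN), associative cortical (ACN), prefrontal (PFN), subcortical
#' (SuCN) and thalamic (ThN) networks -- and to a hemisphere, and records
#' which left/right region pairs are homotopic (mirror-symmetric
#' counterparts). Region ordering alternates left/right within each module,
#' so module-ordered connectivity matrices interleave hemispheres.
#'
#' @slot regions character vector of unique region labels, in matrix order.
#' @slot module character vector, module id per region.
#' @slot hemisphere character vector, `"L"` or `"R"` per region.
#' @slot pairs two-column character matrix; each row one homotopic
#'   (left, right) pair.
#'
#' @aliases regionLabels moduleOf hemisphereOf homotopicPairs
#' @seealso [buildAtlas()]
#' @export
setClass("ModuleAtlas",
  representation(regions = "character", module = "character",
                 hemisphere = "character", pairs = "matrix"))

setValidity("ModuleAtlas", function(object) {
  msg <- NULL
  n <- length(object@regions)
  if (anyDuplicated(object@regions)) msg <- c(msg, "region labels must be unique")
  if (length(object@module) != n || length(object@hemisphere) != n)
    msg <- c(msg, "module and hemisphere must have one entry per region")
  if (!all(object@hemisphere %in% c("L", "R")))
    msg <- c(msg, "hemisphere must be 'L' or 'R'")
  p <- object@pairs
  if (ncol(p) != 2L) msg <- c(msg, "pairs must have two columns")
  else {
    if (anyDuplicated(c(p))) msg <- c(msg, "homotopic pairs must be disjoint")
    if (!all(c(p) %in% object@regions)) msg <- c(msg, "pair members must be atlas regions")
    else {
      iL <- match(p[, 1L], object@regions); iR <- match(p[, 2L], object@regions)
      if (!all(object@hemisphere[iL] == "L" & object@hemisphere[iR] == "R"))
        msg <- c(msg, "each pair must join one L and one R region")
      if (!all(object@module[iL] == object@module[iR]))
        msg <- c(msg, "homotopic partners must share a module")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Build a module atlas with left/right homotopic pairing
#'
#' Constructs an atlas of `sum(moduleSizes)` regions split over the named
#' modules. Each module holds `size/2` homotopic pairs; regions are ordered
#' module by module, alternating left and right within each pair (odd
#' positions left hemisphere, even positions right), which fixes the row and
#' column order of every module-organised connectivity matrix downstream.
#'
#' @param moduleSizes named integer vector of region counts per module; every
#'   count must be even so regions pair across hemispheres. Default: the
#'   24-region five-module layout (LCN 6, ACN 4, PFN 4, SuCN 6, ThN 4).
#' @param regionNames optional base names for the pairs (one per pair, in
#'   module order); default generates `"<module><k>"`.
#' @return a [ModuleAtlas-class] object.
#' @examples
#' atlas <- buildAtlas()
#' length(regionLabels(atlas))   # 24
#' nrow(homotopicPairs(atlas))   # 12
#' @export
buildAtlas <- function(moduleSizes = c(LCN = 6L, ACN = 4L, PFN = 4L,
                                       SuCN = 6L, ThN = 4L),
                       regionNames = NULL) {
  if (is.null(names(moduleSizes)))
    names(moduleSizes) <- paste0("M", seq_along(moduleSizes))
  if (any(moduleSizes <= 0) || any(moduleSizes %% 2L != 0L))
    stop("every module size must be a positive even count (one L and one R region per pair)")
  nPairs <- sum(moduleSizes) / 2L
  if (is.null(regionNames)) {
    regionNames <- unlist(lapply(names(moduleSizes), function(m)
      paste0(m, seq_len(moduleSizes[[m]] / 2L))), use.names = FALSE)
  }
  if (length(regionNames) != nPairs)
    stop("regionNames must supply one base name per homotopic pair")
  regions <- as.vector(rbind(paste0(regionNames, "_L"), paste0(regionNames, "_R")))
  module <- rep(rep(names(moduleSizes), times = moduleSizes / 2L), each = 2L)
  hemisphere <- rep(c("L", "R"), nPairs)
  pairs <- cbind(paste0(regionNames, "_L"), paste0(regionNames, "_R"))
  colnames(pairs) <- c("left", "right")
  new("ModuleAtlas", regions = regions, module = module,
      hemisphere = hemisphere, pairs = pairs)
}

#' @rdname ModuleAtlas-class
setMethod("regionLabels", "ModuleAtlas", function(x) x@regions)

#' @rdname ModuleAtlas-class
setMethod("moduleOf", "ModuleAtlas",
          function(x) setNames(x@module, x@regions))

#' @rdname ModuleAtlas-class
setMethod("hemisphereOf", "ModuleAtlas",
          function(x) setNames(x@hemisphere, x@regions))

#' @rdname ModuleAtlas-class
setMethod("homotopicPairs", "ModuleAtlas", function(x) x@pairs)

setMethod("show", "ModuleAtlas", function(object) {
  cat("ModuleAtlas with", length(object@regions), "regions,",
      nrow(object@pairs), "homotopic pairs\n")
  tab <- table(factor(object@module, levels = unique(object@module)))
  cat("modules:", paste(sprintf("%s(%d)", names(tab), tab), collapse = ", "), "\n")
})

#' Write / read an atlas as JSON
#'
#' @param atlas a [ModuleAtlas-class].
#' @param path file path.
#' @return `writeAtlasJSON` returns `path` invisibly; `readAtlasJSON`
#'   returns a [ModuleAtlas-class].
#' @export
writeAtlasJSON <- function(atlas, path) {
  jsonlite::write_json(list(
    regions = atlas@regions, module = atlas@module,
    hemisphere = atlas@hemisphere,
    pairs = as.data.frame(atlas@pairs, stringsAsFactors = FALSE)),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeAtlasJSON
#' @export
readAtlasJSON <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("ModuleAtlas", regions = j$regions, module = j$module,
      hemisphere = j$hemisphere,
      pairs = as.matrix(j$pairs))
}
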