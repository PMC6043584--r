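#' @rdname ModuleAtlas-class
#' @param x an object.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname ModuleAtlas-class
#' @export
setGeneric("moduleOf", function(x) standardGeneric("moduleOf"))

#' @rdname ModuleAtlas-class
#' @export
setGeneric("hemisphereOf", function(x) standardGeneric("hemisphereOf"))

#' @rdname ModuleAtlas-class
#' @export
setGeneric("homotopicPairs", function(x) standardGeneric("homotopicPairs"))

#' @rdname SubjectTimeSeries-class
#' @export
setGeneric("seriesMatrix", function(x) standardGeneric("seriesMatrix"))

#' @rdname SubjectTimeSeries-class
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname SubjectTimeSeries-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname SubjectTimeSeries-class
#' @export
setGeneric("dose", function(x) standardGeneric("dose"))

#' @rdname FCMatrix-class
#' @export
setGeneric("fcValues", function(x) standardGeneric("fcValues"))

#' @rdname FCMatrix-class
#' @export
setGeneric("fcKind", function(x) standardGeneric("fcKind"))

#' @rdname FCMatrix-class
#' @export
setGeneric("fcScale", function(x) standardGeneric("fcScale"))

#' @rdname WindowStack-class
#' @export
setGeneric("stackMatrix", function(x) standardGeneric("stackMatrix"))

#' @rdname WindowStack-class
#' @export
setGeneric("edgeNames", function(x) standardGeneric("edgeNames"))

#' @rdname StateDictionary-class
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname StateDictionary-class
#' @export
setGeneric("stability", function(x) standardGeneric("stability"))

#' @rdname StateDictionary-class
#' @export
setGeneric("orderingTag", function(x) standardGeneric("orderingTag"))

#' @rdname WeightTimeSeries-class
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))

#' @rdname WeightTimeSeries-class
#' @export
setGeneric("weightSummary", function(x) standardGeneric("weightSummary"))
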