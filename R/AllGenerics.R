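#' @rdname TransectRecord-class
#' @param x,object an object.
#' @export
setGeneric("surveyId", function(x) standardGeneric("surveyId"))

#' @rdname TransectRecord-class
#' @export
setGeneric("surveySite", function(x) standardGeneric("surveySite"))

#' @rdname TransectRecord-class
#' @export
setGeneric("surveyDepth", function(x) standardGeneric("surveyDepth"))

#' @rdname TransectRecord-class
#' @export
setGeneric("surveyAspect", function(x) standardGeneric("surveyAspect"))

#' @rdname TransectRecord-class
#' @export
setGeneric("speciesCodes", function(x) standardGeneric("speciesCodes"))

#' @rdname TransectRecord-class
#' @export
setGeneric("transectLength", function(x) standardGeneric("transectLength"))

#' @rdname BenthicNetwork-class
#' @export
setGeneric("vertexTable", function(x) standardGeneric("vertexTable"))

#' @rdname BenthicNetwork-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname BenthicNetwork-class
#' @export
setGeneric("numVertices", function(x) standardGeneric("numVertices"))

#' Edge count of a co-occurrence network
#'
#' With \code{weighted = TRUE} (the default) edges are counted with their
#' adjacency multiplicity, the convention used for transect summaries; the
#' simple count is what the model operates on.
#'
#' @param x a \linkS4class{BenthicNetwork}.
#' @param weighted count adjacency multiplicities?
#' @return integer edge count.
#' @export
setGeneric("edgeCount", function(x, weighted = TRUE) standardGeneric("edgeCount"))

#' @rdname BenthicNetwork-class
#' @export
setGeneric("isFittable", function(x) standardGeneric("isFittable"))

#' @rdname BenthicNetwork-class
#' @export
setGeneric("asAdjacency", function(x) standardGeneric("asAdjacency"))

#' @rdname BenthicNetwork-class
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname ErgmFit-class
#' @export
setGeneric("stdErrors", function(x) standardGeneric("stdErrors"))

#' @rdname ErgmFit-class
#' @export
setGeneric("zValues", function(x) standardGeneric("zValues"))

#' @rdname ErgmFit-class
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @rdname ErgmFit-class
#' @export
setGeneric("fitFlags", function(x) standardGeneric("fitFlags"))

#' @rdname GofReport-class
#' @export
setGeneric("gofTable", function(x) standardGeneric("gofTable"))

#' @rdname FitBundle-class
#' @export
setGeneric("bundleMetadata", function(x) standardGeneric("bundleMetadata"))

#' @rdname FitBundle-class
#' @export
setGeneric("covariateFit", function(x) standardGeneric("covariateFit"))

#' @rdname FitBundle-class
#' @export
setGeneric("model2Fit", function(x) standardGeneric("model2Fit"))

#' @rdname FitBundle-class
#' @export
setGeneric("usedFallback", function(x) standardGeneric("usedFallback"))

#' @rdname SpeciesEffectTable-class
#' @export
setGeneric("effectTable", function(x) standardGeneric("effectTable"))
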