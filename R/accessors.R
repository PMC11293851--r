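#' @rdname TransectRecord-class
setMethod("surveyId", "TransectRecord", function(x) x@surveyId)
#' @rdname TransectRecord-class
setMethod("surveySite", "TransectRecord", function(x) x@site)
#' @rdname TransectRecord-class
setMethod("surveyDepth", "TransectRecord", function(x) x@depth)
#' @rdname TransectRecord-class
setMethod("surveyAspect", "TransectRecord", function(x) x@aspect)
#' @rdname TransectRecord-class
setMethod("speciesCodes", "TransectRecord", function(x) x@codes)
#' @rdname TransectRecord-class
setMethod("transectLength", "TransectRecord", function(x) length(x@codes))

#' @export
setMethod("show", "TransectRecord", function(object) {
  cat("TransectRecord", object@surveyId, "at", object@site,
      sprintf("(%g m, %s)", object@depth, object@aspect), "\n")
  cat(" ", length(object@codes), "observation points,",
      length(unique(object@codes)), "species\n")
})

#' @rdname BenthicNetwork-class
setMethod("surveyId", "BenthicNetwork", function(x) x@surveyId)
#' @rdname BenthicNetwork-class
setMethod("surveySite", "BenthicNetwork", function(x) x@site)
#' @rdname BenthicNetwork-class
setMethod("surveyDepth", "BenthicNetwork", function(x) x@depth)
#' @rdname BenthicNetwork-class
setMethod("surveyAspect", "BenthicNetwork", function(x) x@aspect)
#' @rdname BenthicNetwork-class
setMethod("vertexTable", "BenthicNetwork", function(x) x@vertices)
#' @rdname BenthicNetwork-class
setMethod("edgeTable", "BenthicNetwork", function(x) x@edges)
#' @rdname BenthicNetwork-class
setMethod("numVertices", "BenthicNetwork", function(x) nrow(x@vertices))

#' @rdname edgeCount
setMethod("edgeCount", "BenthicNetwork", function(x, weighted = TRUE) {
  if (!nrow(x@edges)) return(0L)
  if (weighted) as.integer(sum(x@edges$multiplicity)) else nrow(x@edges)
})

#' @rdname BenthicNetwork-class
setMethod("isFittable", "BenthicNetwork", function(x) nrow(x@vertices) >= 2)

#' @rdname BenthicNetwork-class
setMethod("asAdjacency", "BenthicNetwork", function(x) {
  codes <- x@vertices$code
  n <- length(codes)
  A <- matrix(0L, n, n, dimnames = list(codes, codes))
  if (nrow(x@edges)) {
    iu <- match(x@edges$u, codes); iv <- match(x@edges$v, codes)
    A[cbind(iu, iv)] <- 1L
    A[cbind(iv, iu)] <- 1L
  }
  A
})

#' @rdname BenthicNetwork-class
setMethod("asIgraph", "BenthicNetwork", function(x) {
  g <- igraph::graph_from_data_frame(
    d = if (nrow(x@edges)) x@edges else
      data.frame(u = character(), v = character(),
                 multiplicity = numeric()),
    directed = FALSE, vertices = x@vertices)
  igraph::graph_attr(g, "surveyId") <- x@surveyId
  igraph::graph_attr(g, "site") <- x@site
  igraph::graph_attr(g, "depth") <- x@depth
  igraph::graph_attr(g, "aspect") <- x@aspect
  g
})

#' @export
setMethod("show", "BenthicNetwork", function(object) {
  cat("BenthicNetwork", object@surveyId,
      sprintf("(%s, %g m, %s)\n", object@site, object@depth, object@aspect))
  cat(" ", nrow(object@vertices), "vertices,",
      nrow(object@edges), "simple edges,",
      edgeCount(object, weighted = TRUE), "weighted edges\n")
  if (!isFittable(object)) cat("  [single-species transect: not fittable]\n")
})

#' @export
setMethod("show", "ErgmModel", function(object) {
  cat("ErgmModel: ~", object@formula, "\n")
})

#' @rdname ErgmFit-class
#' @param ... unused.
#' @export
setMethod("coef", "ErgmFit", function(object, ...) object@coef)
#' @rdname ErgmFit-class
setMethod("stdErrors", "ErgmFit", function(x) x@se)
#' @rdname ErgmFit-class
setMethod("zValues", "ErgmFit", function(x) x@z)
#' @rdname ErgmFit-class
setMethod("isConverged", "ErgmFit", function(x) x@converged)
#' @rdname ErgmFit-class
setMethod("fitFlags", "ErgmFit", function(x) x@flags)
#' @rdname ErgmFit-class
#' @export
setMethod("logLik", "ErgmFit", function(object, ...) object@logLik)

#' @export
setMethod("show", "ErgmFit", function(object) {
  cat(sprintf("ErgmFit (%s%s): ~ %s\n", object@method,
              if (object@converged) "" else ", NOT converged",
              object@model@formula))
  tab <- data.frame(estimate = object@coef, se = object@se, z = object@z)
  print(round(tab, 4))
  cat(sprintf("  logLik %.3f  AIC %.2f  BIC %.2f\n",
              object@logLik, object@aic, object@bic))
  if (isTRUE(object@flags$separation))
    cat("  [separation detected in pseudolikelihood]\n")
  if (isTRUE(object@flags$degenerate))
    cat("  [degenerate simulated distribution]\n")
})

#' @rdname GofReport-class
setMethod("gofTable", "GofReport", function(x) x@stats)

#' @export
setMethod("show", "GofReport", function(object) {
  cat("GofReport over", object@nSim, "simulated networks\n")
  print(round(object@stats[, c("observed", "simMean", "simSd", "p")], 4))
})

#' @rdname FitBundle-class
setMethod("bundleMetadata", "FitBundle", function(x) x@metadata)
#' @rdname FitBundle-class
setMethod("covariateFit", "FitBundle", function(x) x@covariateFit)
#' @rdname FitBundle-class
setMethod("model2Fit", "FitBundle", function(x) x@model2Fit)
#' @rdname FitBundle-class
setMethod("usedFallback", "FitBundle", function(x) x@fallback)

#' @export
setMethod("show", "FitBundle", function(object) {
  md <- object@metadata
  cat("FitBundle", md$surveyId %||% "?",
      sprintf("(%s, %s m): covariate model %s%s\n", md$site %||% "?",
              md$depth %||% "?", object@covariateModel,
              if (object@fallback) " [fallback]" else ""))
})

#' @export
setMethod("show", "CommunityModel", function(object) {
  cat("CommunityModel:", length(object@species), "species, transect",
      object@transectLength, "cm, mean run", object@runLengthMean,
      "cm, triad propensity", object@triadProp, "\n")
  planted <- sum(object@affinity[upper.tri(object@affinity)] != 1)
  cat(" ", planted, "planted non-neutral pair(s)\n")
})

#' @rdname SpeciesEffectTable-class
setMethod("effectTable", "SpeciesEffectTable", function(x) x@table)

#' @export
setMethod("show", "SpeciesEffectTable", function(object) {
  cat("SpeciesEffectTable:", nrow(object@table), "species above the",
      sprintf("> %g-network occurrence filter (%d total)\n",
              object@minOccurrences, length(object@raw)))
  print(head(object@table, 10))
})
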