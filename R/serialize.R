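## JSON/CSV serialization of fits and bundles.

fitToList <- function(fit) {
  list(formula = fit@model@formula, method = fit@method,
       terms = names(coef(fit)), estimate = unname(coef(fit)),
       se = unname(stdErrors(fit)), z = unname(zValues(fit)),
       logLik = fit@logLik, logNormalizer = fit@logNormalizer,
       aic = fit@aic, bic = fit@bic, converged = fit@converged,
       seed = fit@seed,
       separation = isTRUE(fit@flags$separation),
       degenerate = isTRUE(fit@flags$degenerate),
       mcmcSummary = fit@mcmcSummary)
}

#' Serialize a fit or bundle to JSON
#'
#' @param x an \linkS4class{ErgmFit} or \linkS4class{FitBundle}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFitJson <- function(x, path) {
  obj <- if (is(x, "ErgmFit")) fitToList(x)
  else if (is(x, "FitBundle")) {
    list(metadata = x@metadata[setdiff(names(x@metadata), "species")],
         species = x@metadata$species,
         covariateModel = x@covariateModel, fallback = x@fallback,
         covariateFit = if (!is.null(x@covariateFit))
           fitToList(x@covariateFit),
         model2Fit = if (!is.null(x@model2Fit)) fitToList(x@model2Fit),
         gofCovariate = if (!is.null(x@gofCovariate))
           x@gofCovariate@stats,
         gofModel2 = if (!is.null(x@gofModel2)) x@gofModel2@stats)
  } else stop("cannot serialize objects of class ", class(x)[1])
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Flatten fit bundles to one row per (network, model, term)
#'
#' @param bundles list of \linkS4class{FitBundle}s.
#' @return data.frame with estimate, SE, z, AIC, BIC, GoF p and fallback
#'   flag per term.
#' @export
bundleTable <- function(bundles) {
  one <- function(b, fit, gofRep, modelName) {
    if (is.null(fit)) return(NULL)
    gp <- if (!is.null(gofRep))
      setNames(gofRep@stats$p, gofRep@stats$term) else numeric(0)
    md <- bundleMetadata(b)
    data.frame(surveyId = md$surveyId, site = md$site, depth = md$depth,
               model = modelName, term = names(coef(fit)),
               estimate = unname(coef(fit)), se = unname(stdErrors(fit)),
               z = unname(zValues(fit)), aic = fit@aic, bic = fit@bic,
               gofP = unname(gp[names(coef(fit))]),
               converged = fit@converged, fallback = usedFallback(b),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- do.call(rbind, unlist(lapply(bundles, function(b) list(
    one(b, b@covariateFit, b@gofCovariate, b@covariateModel),
    one(b, b@model2Fit, b@gofModel2, "model2"))),
    recursive = FALSE))
  rownames(out) <- NULL
  out
}
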