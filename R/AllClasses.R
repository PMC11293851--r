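#' @import methods
NULL

ASPECT_LEVELS <- c("photophilous", "sciaphilous", "unknown")

#' TransectRecord: one per-centimetre benthic survey line
#'
#' Holds the ordered species codes observed along a single transect
#' (one code per centimetre, 1-based positions) together with its survey
#' metadata.  The study design records 500 points per 5 m transect, but any
#' positive length is accepted.
#'
#' @slot surveyId survey label, e.g. \code{"DO2.E"}.
#' @slot site site label.
#' @slot depth depth in metres.
#' @slot aspect one of \code{"photophilous"}, \code{"sciaphilous"},
#'   \code{"unknown"} (sunlit vs shaded reef wall).
#' @slot codes character vector of species codes, one per centimetre.
#' @export
setClass("TransectRecord",
  representation(surveyId = "character", site = "character",
                 depth = "numeric", aspect = "character",
                 codes = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@codes) < 1) msg <- c(msg, "codes must be non-empty")
    if (any(!nzchar(object@codes) & !is.na(object@codes)) ||
        anyNA(object@codes))
      msg <- c(msg, "every species code must be a non-empty string")
    if (length(object@depth) != 1 || is.na(object@depth) || object@depth <= 0)
      msg <- c(msg, "depth must be a single positive number")
    if (!object@aspect %in% ASPECT_LEVELS)
      msg <- c(msg, "aspect must be photophilous, sciaphilous or unknown")
    if (length(msg)) msg else TRUE
  })

#' Construct a TransectRecord
#'
#' @param surveyId,site,depth,aspect survey metadata; unrecognised aspects
#'   map to \code{"unknown"}.
#' @param codes character vector of per-centimetre species codes
#'   (whitespace is stripped; codes are case-sensitive).
#' @return A \linkS4class{TransectRecord}.
#' @examples
#' tr <- transectRecord("T1", "siteA", 7, "photophilous",
#'                      strsplit("AAAAABBBBCCAA", "")[[1]])
#' transectLength(tr)
#' @export
transectRecord <- function(surveyId, site, depth, aspect, codes) {
  aspect <- as.character(aspect)
  if (is.na(aspect) || !aspect %in% ASPECT_LEVELS) aspect <- "unknown"
  new("TransectRecord", surveyId = as.character(surveyId),
      site = as.character(site), depth = as.numeric(depth),
      aspect = aspect, codes = trimws(as.character(codes)))
}

#' BenthicNetwork: an undirected species co-occurrence graph
#'
#' Vertices are species observed on one transect, with quantitative
#' covariates \code{size} (total centimetres occupied) and \code{count}
#' (number of runs) plus a \code{phylum} label.  Edges join species whose
#' runs share a boundary; \code{multiplicity} counts the distinct adjacency
#' observations.  Model fitting uses the simple graph; multiplicities are
#' descriptive and feed the weighted edge totals.
#'
#' @slot vertices data.frame with columns code, size, count, phylum.
#' @slot edges data.frame with columns u, v, multiplicity (u < v as strings).
#' @slot surveyId,site,aspect character metadata.
#' @slot depth numeric depth (m).
#' @export
setClass("BenthicNetwork",
  representation(vertices = "data.frame", edges = "data.frame",
                 surveyId = "character", site = "character",
                 depth = "numeric", aspect = "character"),
  validity = function(object) {
    v <- object@vertices; e <- object@edges
    msg <- character()
    if (!all(c("code", "size", "count", "phylum") %in% names(v)))
      msg <- c(msg, "vertices needs columns code, size, count, phylum")
    if (!all(c("u", "v", "multiplicity") %in% names(e)))
      msg <- c(msg, "edges needs columns u, v, multiplicity")
    if (anyDuplicated(v$code)) msg <- c(msg, "duplicate vertex codes")
    if (nrow(e)) {
      if (any(e$u == e$v)) msg <- c(msg, "self-loops are not allowed")
      if (any(e$multiplicity < 1)) msg <- c(msg, "edge multiplicity must be >= 1")
      if (!all(c(e$u, e$v) %in% v$code))
        msg <- c(msg, "edge endpoints must be vertices")
      if (anyDuplicated(paste(pmin(e$u, e$v), pmax(e$u, e$v))))
        msg <- c(msg, "duplicate edges; accumulate multiplicities instead")
    }
    if (length(msg)) msg else TRUE
  })

#' ErgmModel: an ordered ERGM term configuration
#'
#' Terms are one of \code{edges}, \code{gwesp(decay, fixed)},
#' \code{nodecov(attr)}, \code{nodefactor(attr)}.  See
#' \code{\link{ergmModel}}.
#'
#' @slot terms list of term descriptors.
#' @slot formula the parsed model string.
#' @export
setClass("ErgmModel",
  representation(terms = "list", formula = "character"),
  validity = function(object) {
    kinds <- vapply(object@terms, function(t) t$type, "")
    keys <- vapply(object@terms, function(t)
      paste(t$type, t$attr %||% "", sep = ":"), "")
    msg <- character()
    if (!length(object@terms)) msg <- c(msg, "model needs at least one term")
    if (anyDuplicated(keys)) msg <- c(msg, "duplicate model terms")
    for (t in object@terms)
      if (t$type == "gwesp" && t$decay < 0)
        msg <- c(msg, "gwesp decay must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' ErgmFit: a fitted exponential random graph model
#'
#' @slot model the \linkS4class{ErgmModel}.
#' @slot coef named coefficient vector (one per expanded term).
#' @slot se,z standard errors and z-values (theta / SE); NA where a
#'   simulated statistic had zero variance.
#' @slot logLik log-likelihood (exact for dyad-independent models, path
#'   sampled for MCMC fits); NA when not estimable.
#' @slot logNormalizer log k(theta) - log k(0).
#' @slot aic,bic information criteria (D = number of dyads is the BIC
#'   sample size).
#' @slot converged logical convergence flag.
#' @slot method one of \code{"exact"}, \code{"mple"}, \code{"mcmle"}.
#' @slot mcmcSummary data.frame of per-term simulated means/sds/t-ratios
#'   at the final iteration (empty for dyad-independent fits).
#' @slot seed integer seed used (NA if none supplied).
#' @slot flags list: separation, degenerate, notEstimable, direction.
#' @export
setClass("ErgmFit",
  representation(model = "ErgmModel", coef = "numeric", se = "numeric",
                 z = "numeric", logLik = "numeric",
                 logNormalizer = "numeric", aic = "numeric", bic = "numeric",
                 converged = "logical", method = "character",
                 mcmcSummary = "data.frame", seed = "integer",
                 flags = "list"))

#' GofReport: simulation-based goodness of fit for one fitted model
#'
#' @slot stats data.frame with per-term observed value, simulated mean/sd
#'   and a two-sided Monte-Carlo p-value (add-one corrected, capped at 1;
#'   high p indicates the simulated networks reproduce the observed
#'   statistic).
#' @slot degree observed degree distribution and simulated quantiles.
#' @slot esp observed edgewise-shared-partner distribution and simulated
#'   quantiles.
#' @slot nSim number of simulated networks.
#' @slot seed integer seed.
#' @export
setClass("GofReport",
  representation(stats = "data.frame", degree = "list", esp = "list",
                 nSim = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSim < 1) msg <- c(msg, "nSim must be >= 1")
    p <- object@stats$p
    if (length(p) && any(!is.na(p) & (p <= 0 | p > 1)))
      msg <- c(msg, "p-values must lie in (0, 1]")
    if (length(msg)) msg else TRUE
  })

setClassUnion("ErgmFitOrNULL", c("ErgmFit", "NULL"))
setClassUnion("GofReportOrNULL", c("GofReport", "NULL"))

#' FitBundle: all model fits and diagnostics for one network
#'
#' Bundles the covariate model (the triad model, or its covariate-only
#' restriction when the triad model degenerates or fails to converge), the
#' species-factor model, and their goodness-of-fit reports.
#'
#' @slot metadata list: surveyId, site, depth, aspect, nVertices,
#'   nEdgesWeighted, nEdgesSimple.
#' @slot covariateFit the fitted covariate model (or NULL when not
#'   estimable).
#' @slot covariateModel \code{"model1"} or \code{"model1A"}.
#' @slot fallback TRUE iff the covariate-only restriction was used.
#' @slot model2Fit species-factor fit (or NULL).
#' @slot gofCovariate,gofModel2 goodness-of-fit reports (or NULL).
#' @slot diagnostics list of degeneracy/MCMC diagnostics.
#' @export
setClass("FitBundle",
  representation(metadata = "list", covariateFit = "ErgmFitOrNULL",
                 covariateModel = "character", fallback = "logical",
                 model2Fit = "ErgmFitOrNULL",
                 gofCovariate = "GofReportOrNULL",
                 gofModel2 = "GofReportOrNULL", diagnostics = "list"),
  validity = function(object) {
    if (!object@covariateModel %in% c("model1", "model1A", "none"))
      return("covariateModel must be model1, model1A or none")
    if (object@fallback && object@covariateModel == "model1")
      return("fallback bundles must carry the restricted model")
    TRUE
  })

#' CommunityModel: generative model for synthetic transects
#'
#' @slot species species codes.
#' @slot abundance base abundance weights (sum to 1).
#' @slot affinity symmetric positive pairwise affinity matrix; 1 neutral,
#'   >1 attraction, <1 avoidance; diagonal ignored.
#' @slot triadProp probability in \[0, 1) of a triangle-closing move.
#' @slot runLengthMean mean run length in centimetres (geometric runs).
#' @slot transectLength transect length in centimetres.
#' @slot phylum phylum label per species.
#' @export
setClass("CommunityModel",
  representation(species = "character", abundance = "numeric",
                 affinity = "matrix", triadProp = "numeric",
                 runLengthMean = "numeric", transectLength = "numeric",
                 phylum = "character"),
  validity = function(object) {
    msg <- character()
    k <- length(object@species)
    if (k < 2) msg <- c(msg, "need at least 2 species")
    if (abs(sum(object@abundance) - 1) > 1e-8)
      msg <- c(msg, "abundances must sum to 1")
    if (!isTRUE(all.equal(object@affinity, t(object@affinity))))
      msg <- c(msg, "affinity matrix must be symmetric")
    if (any(object@affinity <= 0)) msg <- c(msg, "affinities must be positive")
    if (object@triadProp < 0 || object@triadProp >= 1)
      msg <- c(msg, "triadProp must lie in [0, 1)")
    if (object@runLengthMean < 1) msg <- c(msg, "runLengthMean must be >= 1")
    if (length(msg)) msg else TRUE
  })

#' SpeciesEffectTable: species-factor effects pooled across networks
#'
#' @slot table data.frame (one row per species passing the occurrence
#'   filter): code, n, medianZ, meanZ, meanCoef, medianCoef and, after
#'   \code{\link{classifyPreferences}}, a label column.
#' @slot raw named list of per-species data.frames (all species) with one
#'   row per contributing network: surveyId, estimate, z.
#' @slot minOccurrences the occurrence filter applied to \code{table}.
#' @export
setClass("SpeciesEffectTable",
  representation(table = "data.frame", raw = "list",
                 minOccurrences = "numeric"))
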