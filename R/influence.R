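## Relative influence of survey design factors on triad goodness of fit,
## via a seeded random forest with permutation importance.

#' Assemble the predictor table for the influence analysis
#'
#' One row per network with a non-fallback triad-model fit: site, depth,
#' aspect, vertex count, multiplicity-weighted edge count, and the gwesp
#' goodness-of-fit p-value as the response.  Fallback-only networks are
#' excluded (a message reports how many).
#'
#' @param bundles list of \linkS4class{FitBundle}s.
#' @return data.frame with columns site, depth, aspect, nVertices,
#'   nEdges, response.
#' @export
assemblePredictorTable <- function(bundles) {
  rows <- lapply(bundles, function(b) {
    if (b@covariateModel != "model1" || is.null(b@gofCovariate)) return(NULL)
    gs <- gofTable(b@gofCovariate)
    pg <- gs$p[startsWith(gs$term, "gwesp")]
    if (length(pg) != 1) return(NULL)
    md <- bundleMetadata(b)
    data.frame(site = as.character(md$site %||% "unknown"),
               depth = as.numeric(md$depth %||% NA),
               aspect = as.character(md$aspect %||% "unknown"),
               nVertices = md$nVertices, nEdges = md$nEdgesWeighted,
               response = pg, stringsAsFactors = FALSE)
  })
  excluded <- sum(vapply(rows, is.null, TRUE))
  if (excluded) message(excluded, " fallback-only network(s) excluded")
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 2)
    stop("need at least 2 networks with a model-1 goodness of fit")
  tab$site <- factor(tab$site)
  tab$aspect <- factor(ifelse(is.na(tab$aspect) | !nzchar(tab$aspect),
                              "unknown", tab$aspect))
  rownames(tab) <- NULL
  tab
}

#' Relative influence of predictors on the triad goodness of fit
#'
#' Fits a random forest of \code{response} on every other column of the
#' table and reports permutation importances normalized to percentages
#' (negative raw importances are floored at zero).  A constant response
#' yields uniform shares with a warning.
#'
#' @param table a predictor table from
#'   \code{\link{assemblePredictorTable}} (any data.frame with a
#'   \code{response} column works).
#' @param nTrees number of trees.
#' @param mtry candidate predictors per split; the default, half the
#'   predictors (at least 2, at most all), lets trees prefer the truly
#'   informative variable — the sparser regression default of p/3 dilutes
#'   permutation importance across correlated survey covariates.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return List with \code{importance} (named percentages summing to
#'   100) and \code{forest} (the fitted ensemble, for
#'   \code{\link{partialDependence}}), carrying the training table as
#'   attribute.
#' @export
relativeInfluence <- function(table, nTrees = 500, mtry = NULL,
                              seed = NULL) {
  stopifnot(is.data.frame(table), "response" %in% names(table),
            nrow(table) >= 2)
  predictors <- setdiff(names(table), "response")
  if (!length(predictors)) stop("no predictor columns")
  uniform <- setNames(rep(100 / length(predictors), length(predictors)),
                      predictors)
  if (var(table$response) == 0) {
    warning("constant response: uniform importances returned")
    return(list(importance = uniform, forest = NULL, table = table))
  }
  mtry <- mtry %||% min(max(2L, floor(length(predictors) / 2)),
                        length(predictors))
  rf <- withSeed(seed, randomForest::randomForest(
    response ~ ., data = table, ntree = nTrees, mtry = mtry,
    importance = TRUE))
  raw <- randomForest::importance(rf, type = 1)
  raw <- setNames(raw[, 1], rownames(raw))
  imp <- setNames(rep(0, length(predictors)), predictors)
  hit <- intersect(names(raw), predictors)
  imp[hit] <- pmax(raw[hit], 0)
  imp[is.na(imp)] <- 0
  if (sum(imp) <= 0) {
    warning("no positive importances: uniform shares returned")
    return(list(importance = uniform, forest = rf, table = table))
  }
  list(importance = 100 * imp / sum(imp), forest = rf, table = table)
}

#' Univariate partial dependence of the fitted ensemble
#'
#' Mean ensemble prediction over the training table with one predictor
#' clamped to each grid value.
#'
#' @param influence result of \code{\link{relativeInfluence}}.
#' @param predictor predictor column name.
#' @param grid values to clamp the predictor to; defaults to the factor
#'   levels or 25 quantile points.
#' @return data.frame with columns \code{value} and \code{prediction}.
#' @export
partialDependence <- function(influence, predictor, grid = NULL) {
  tab <- influence$table
  if (!predictor %in% setdiff(names(tab), "response"))
    stop("unknown predictor: ", predictor)
  if (is.null(influence$forest)) stop("no fitted ensemble available")
  x <- tab[[predictor]]
  if (is.null(grid)) {
    grid <- if (is.factor(x)) levels(x)
            else unique(quantile(x, seq(0, 1, length.out = 25), names = FALSE))
  }
  preds <- vapply(grid, function(v) {
    nd <- tab
    nd[[predictor]] <- if (is.factor(x))
      factor(rep(as.character(v), nrow(nd)), levels = levels(x))
    else as.numeric(v)
    mean(predict(influence$forest, newdata = nd))
  }, 0)
  data.frame(value = grid, prediction = preds,
             stringsAsFactors = FALSE, row.names = NULL)
}
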