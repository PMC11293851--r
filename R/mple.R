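## Maximum pseudolikelihood: logistic regression of each dyad's edge
## indicator on its change statistics in the observed graph.  For
## dyad-independent models (no gwesp) this IS the maximum likelihood
## estimate and the logistic log-likelihood is the exact graph
## log-likelihood.

#' Maximum pseudolikelihood estimate
#'
#' Fits the logistic model \eqn{\mathrm{logit}\,P(y_{ij} = 1) = \theta'
#' \Delta g_{ij}} over all dyads.  Used as the starting value for
#' \code{\link{mcmle}}; for dyad-independent models the pseudolikelihood
#' equals the likelihood, so the fit is exact and carries AIC/BIC.
#' Perfect separation (e.g. a complete or empty graph, or a species
#' connected to every co-occurring species under a factor model) is
#' flagged, with the direction of divergence per affected coefficient; the
#' divergent coefficients are retained as fitted.
#'
#' @param network a fittable \linkS4class{BenthicNetwork}.
#' @param model an \linkS4class{ErgmModel}.
#' @param seed optional seed recorded on the fit (the fit itself is
#'   deterministic).
#' @return An \linkS4class{ErgmFit} with \code{method = "mple"}.
#' @export
mple <- function(network, model, seed = NULL) {
  stopifnot(is(network, "BenthicNetwork"))
  if (!isFittable(network))
    stop("network is not fittable (fewer than 2 vertices)")
  ex <- expandTerms(model, network@vertices)
  des <- cpp_dyad_design(asAdjacency(network), ex)
  X <- des$X; colnames(X) <- termNames(ex)
  y <- des$y
  D <- length(y)

  sepWarn <- FALSE
  fit <- withCallingHandlers(
    glm.fit(X, y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sepWarn <<- TRUE
      invokeRestart("muffleWarning")
    })
  th <- setNames(fit$coefficients, colnames(X))
  th[is.na(th)] <- 0

  ## covariance from the information of the logistic fit
  p <- fit$fitted.values
  wt <- p * (1 - p)
  I <- crossprod(X * wt, X)
  se <- rep(NA_real_, length(th))
  V <- tryCatch(solve(I), error = function(e) NULL)
  if (!is.null(V)) se <- sqrt(pmax(diag(V), 0))

  diverged <- abs(th) > 10 & (is.na(se) | se > 50)
  separation <- sepWarn || any(diverged) || all(y == 1) || all(y == 0)
  direction <- setNames(sign(th[diverged]) * Inf,
                        names(th)[diverged])
  if (all(y == 1)) direction <- c(direction, edges = Inf)
  if (all(y == 0)) direction <- c(direction, edges = -Inf)

  dyadInd <- isDyadIndependent(model)
  ll <- NA_real_; logNorm <- NA_real_
  if (dyadInd) {
    eta <- as.vector(X %*% th)
    ll <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
    g <- setNames(as.vector(crossprod(X, y)), colnames(X))
    logNorm <- sum(th * g) - ll - D * log(2)
  }
  fitObject(model = model, coef = th, se = se, logLik = ll,
            logNormalizer = logNorm, nDyads = D,
            converged = isTRUE(fit$converged) && !separation,
            method = "mple", seed = seed,
            flags = list(separation = separation,
                         notEstimable = separation && !dyadInd,
                         direction = direction))
}
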