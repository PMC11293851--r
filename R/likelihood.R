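## Exact small-graph likelihood by exhaustive enumeration.  A graph on n
## vertices has 2^(n(n-1)/2) labelled realizations; up to n = 7 these can
## be enumerated outright, which gives the test oracle for the Monte-Carlo
## estimator.

ENUM_MAX_N <- 7L

enumStats <- function(network, model) {
  n <- numVertices(network)
  if (n > ENUM_MAX_N)
    stop("exact enumeration supports n <= ", ENUM_MAX_N,
         " vertices; use mcmle() for larger networks")
  ex <- expandTerms(model, network@vertices)
  M <- cpp_enumerate_stats(n, ex)
  colnames(M) <- termNames(ex)
  M
}

#' Exact ERGM log-likelihood by enumeration
#'
#' Computes \eqn{\theta' g(y) - \log \sum_{y'} \exp(\theta' g(y'))} by
#' summing over every labelled graph on the network's vertices.  Only
#' feasible for n <= 7; larger networks must use \code{\link{mcmle}}.
#'
#' @param network a \linkS4class{BenthicNetwork} with n <= 7 vertices.
#' @param model an \linkS4class{ErgmModel}.
#' @param theta coefficient vector (one per expanded term).
#' @return The exact log-likelihood.
#' @export
exactLoglik <- function(network, model, theta) {
  M <- enumStats(network, model)
  g <- computeStatistics(network, model)
  stopifnot(length(theta) == ncol(M))
  sum(theta * g) - logSumExp(as.vector(M %*% theta))
}

#' Exact maximum likelihood by enumeration
#'
#' Maximizes the exact likelihood numerically; standard errors come from
#' the exact covariance of the statistics at the optimum (the Fisher
#' information of an exponential family).
#'
#' @inheritParams exactLoglik
#' @return An \linkS4class{ErgmFit} with \code{method = "exact"}.
#' @export
exactMLE <- function(network, model) {
  M <- enumStats(network, model)
  g <- computeStatistics(network, model)
  D <- numVertices(network) * (numVertices(network) - 1) / 2
  p <- ncol(M)
  negll <- function(th) logSumExp(as.vector(M %*% th)) - sum(th * g)
  grad <- function(th) {
    lw <- as.vector(M %*% th); w <- exp(lw - logSumExp(lw))
    as.vector(crossprod(M, w)) - g
  }
  opt <- optim(numeric(p), negll, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  th <- opt$par
  lw <- as.vector(M %*% th); w <- exp(lw - logSumExp(lw))
  Eg <- as.vector(crossprod(M, w))
  Egg <- crossprod(M, M * w)
  I <- Egg - tcrossprod(Eg)
  se <- rep(NA_real_, p)
  ok <- diag(I) > 1e-12
  if (any(ok)) {
    Vok <- tryCatch(solve(I[ok, ok, drop = FALSE]),
                    error = function(e) NULL)
    if (!is.null(Vok)) se[ok] <- sqrt(pmax(diag(Vok), 0))
  }
  ll <- -opt$value
  fitObject(model = model, coef = setNames(th, colnames(M)), se = se,
            logLik = ll,
            logNormalizer = logSumExp(lw) - D * log(2),
            nDyads = D, converged = opt$convergence == 0,
            method = "exact")
}

## Shared ErgmFit assembly: z, AIC (2p - 2l) and BIC (p log D - 2l).
fitObject <- function(model, coef, se, logLik, logNormalizer, nDyads,
                      converged, method, mcmcSummary = NULL, seed = NULL,
                      flags = list()) {
  p <- length(coef)
  z <- ifelse(!is.na(se) & se > 0, coef / se, NA_real_)
  aic <- if (is.na(logLik)) NA_real_ else 2 * p - 2 * logLik
  bic <- if (is.na(logLik)) NA_real_ else p * log(nDyads) - 2 * logLik
  flags <- modifyList(list(separation = FALSE, degenerate = FALSE,
                           notEstimable = FALSE,
                           direction = setNames(numeric(0), character(0))),
                      flags)
  new("ErgmFit", model = model, coef = coef, se = setNames(se, names(coef)),
      z = setNames(z, names(coef)), logLik = logLik,
      logNormalizer = logNormalizer, aic = aic, bic = bic,
      converged = converged, method = method,
      mcmcSummary = mcmcSummary %||% data.frame(),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      flags = flags)
}

#' Information criteria of a fitted model
#'
#' AIC = 2p - 2 logLik; BIC = p log(D) - 2 logLik with D = n(n-1)/2 dyads
#' as the effective sample size.  The null reference log-likelihood is the
#' exact \eqn{-D \log 2} of the uniform model, so criteria are comparable
#' across estimation methods.
#'
#' @param fit an \linkS4class{ErgmFit}.
#' @return Named vector \code{c(aic, bic)} (NA when the log-likelihood is
#'   not estimable).
#' @export
informationCriteria <- function(fit) {
  stopifnot(is(fit, "ErgmFit"))
  c(aic = fit@aic, bic = fit@bic)
}
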