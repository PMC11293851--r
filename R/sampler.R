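## Metropolis-Hastings simulation of networks from a specified ERGM.

#' Control parameters for simulation and Monte-Carlo estimation
#'
#' Defaults follow the number of dyads D = n(n-1)/2: burn-in of 10 D
#' toggles and thinning of D toggles between retained networks, with 1000
#' retained networks per estimation iteration.  \code{tRatioTol} is the
#' convergence criterion on the per-term t-ratio |observed - simulated
#' mean| / simulated sd; \code{bridges}/\code{bridgeSamples} control the
#' path-sampled log-likelihood.
#'
#' @param burnin,thin toggle counts (NULL = the D-based defaults).
#' @param nSamples retained networks per iteration.
#' @param maxIter maximum Monte-Carlo MLE iterations.
#' @param tRatioTol convergence tolerance on all per-term t-ratios.
#' @param stepMax largest coefficient move per iteration.
#' @param bridges,bridgeSamples path-sampling grid size and networks per
#'   grid point for the log-likelihood estimate.
#' @return A named list of control values.
#' @export
ergmControl <- function(burnin = NULL, thin = NULL, nSamples = 1000,
                        maxIter = 60, tRatioTol = 0.1, stepMax = 2,
                        bridges = 8, bridgeSamples = 256) {
  stopifnot(nSamples >= 1, maxIter >= 1, tRatioTol > 0, stepMax > 0,
            bridges >= 1, bridgeSamples >= 1)
  list(burnin = burnin, thin = thin, nSamples = nSamples,
       maxIter = maxIter, tRatioTol = tRatioTol, stepMax = stepMax,
       bridges = bridges, bridgeSamples = bridgeSamples)
}

resolveControl <- function(control, D) {
  control$burnin <- as.integer(control$burnin %||% (10 * D))
  control$thin <- as.integer(control$thin %||% D)
  stopifnot(control$burnin >= 0, control$thin >= 1)
  control
}

## Low-level wrapper; A0 integer adjacency, ex expanded terms.
mhSample <- function(A0, ex, theta, burnin, thin, nsamp,
                     returnGraphs = FALSE) {
  res <- cpp_mh_sample(A0, ex, theta, as.integer(burnin),
                       as.integer(thin), as.integer(nsamp), returnGraphs)
  colnames(res$stats) <- termNames(ex)
  res
}

#' Simulate networks from an ERGM by Metropolis-Hastings
#'
#' Runs a Markov chain over single-dyad toggles with uniform dyad
#' proposals; a toggle changing the statistics by \eqn{\Delta g} is
#' accepted with probability \eqn{\min(1, \exp(s\,\theta'\Delta g))}, s =
#' +1 for an addition and -1 for a deletion.  Networks are recorded every
#' \code{thin} toggles after \code{burnin}.
#'
#' @param model an \linkS4class{ErgmModel}.
#' @param theta coefficient vector (one per expanded term).
#' @param vertices vertex covariate data.frame (code, size, count, phylum
#'   as required by the model's terms), or a \linkS4class{BenthicNetwork}
#'   whose vertices and observed graph seed the chain.
#' @param control see \code{\link{ergmControl}}.
#' @param seed integer seed (the chain uses R's RNG).
#' @param start optional starting adjacency matrix; defaults to the
#'   observed graph when \code{vertices} is a network, else empty.
#' @return List with \code{graphs} (list of 0/1 adjacency matrices) and
#'   \code{stats} (matrix of sampled statistic vectors, one row per
#'   network).
#' @export
sampleNetworks <- function(model, theta, vertices,
                           control = ergmControl(), seed = NULL,
                           start = NULL) {
  if (is(vertices, "BenthicNetwork")) {
    if (is.null(start)) start <- asAdjacency(vertices)
    vertices <- vertices@vertices
  }
  stopifnot(is.data.frame(vertices))
  n <- nrow(vertices)
  if (n < 2) stop("need at least 2 vertices to simulate")
  ex <- expandTerms(model, vertices)
  stopifnot(length(theta) == length(ex))
  D <- n * (n - 1) / 2
  control <- resolveControl(control, D)
  A0 <- if (is.null(start)) {
    matrix(0L, n, n, dimnames = list(vertices$code, vertices$code))
  } else {
    storage.mode(start) <- "integer"; start
  }
  res <- withSeed(seed, mhSample(A0, ex, theta, control$burnin,
                                 control$thin, control$nSamples,
                                 returnGraphs = TRUE))
  graphs <- lapply(res$graphs, function(A) {
    dimnames(A) <- list(vertices$code, vertices$code); A
  })
  list(graphs = graphs, stats = res$stats)
}
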