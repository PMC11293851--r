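## Simulation-based goodness of fit, degeneracy detection and MCMC trace
## diagnostics.

espCounts <- function(A) {
  n <- nrow(A)
  if (n < 2 || sum(A) == 0) return(integer(0))
  CN <- A %*% A
  CN[upper.tri(CN)][A[upper.tri(A)] == 1]
}

distSummary <- function(observedCounts, simCounts, maxK) {
  ## tabulate counts 0..maxK for observed and each simulated network
  tab <- function(x) tabulate(pmin(x, maxK) + 1L, nbins = maxK + 1L)
  obs <- tab(observedCounts)
  sims <- vapply(simCounts, tab, integer(maxK + 1L))
  list(k = 0:maxK, observed = obs,
       simMean = rowMeans(sims),
       simLo = apply(sims, 1, quantile, 0.025),
       simHi = apply(sims, 1, quantile, 0.975))
}

#' Goodness of fit by simulation
#'
#' Simulates \code{nSim} networks at the fitted coefficients and compares
#' each model statistic of the observed network with its simulated
#' distribution.  The per-term p-value is the two-sided Monte-Carlo
#' \eqn{p = 2\min(r, 1-r)} with the add-one-corrected upper tail \eqn{r =
#' (1 + \#\{sim \ge obs\}) / (n_{sim} + 1)}, capped at 1; a high p means
#' the fitted model reproduces the observed statistic.  Degree and
#' edgewise-shared-partner distributions of the simulated networks are
#' attached as auxiliary checks.
#'
#' @param fit an \linkS4class{ErgmFit}.
#' @param network the observed \linkS4class{BenthicNetwork}.
#' @param nSim number of simulated networks (>= 1).
#' @param seed integer seed.
#' @param control see \code{\link{ergmControl}}; \code{nSamples} is
#'   overridden by \code{nSim}.
#' @return A \linkS4class{GofReport}.
#' @export
gof <- function(fit, network, nSim = 100, seed = NULL,
                control = ergmControl()) {
  stopifnot(is(fit, "ErgmFit"), is(network, "BenthicNetwork"))
  if (nSim < 1) stop("nSim must be >= 1")
  ex <- expandTerms(fit@model, network@vertices)
  nm <- termNames(ex)
  A <- asAdjacency(network)
  D <- nrow(A) * (nrow(A) - 1) / 2
  control <- resolveControl(control, D)
  g <- setNames(as.numeric(cpp_network_stats(A, ex)), nm)
  res <- withSeed(seed, mhSample(A, ex, coef(fit), control$burnin,
                                 control$thin, as.integer(nSim),
                                 returnGraphs = TRUE))
  S <- res$stats
  r <- vapply(seq_along(nm), function(k)
    (1 + sum(S[, k] >= g[k])) / (nSim + 1), 0)
  pvals <- pmin(2 * pmin(r, 1 - r), 1)
  pvals <- pmax(pvals, 2 / (nSim + 1))   # add-one floor; never 0
  stats <- data.frame(term = nm, observed = g, simMean = colMeans(S),
                      simSd = apply(S, 2, sd), p = pvals,
                      stringsAsFactors = FALSE, row.names = NULL)
  n <- nrow(A)
  degs <- lapply(res$graphs, rowSums)
  degree <- distSummary(rowSums(A), degs, maxK = n - 1)
  esp <- distSummary(espCounts(A), lapply(res$graphs, espCounts),
                     maxK = max(1L, n - 2L))
  new("GofReport", stats = stats, degree = degree, esp = esp,
      nSim = as.integer(nSim),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Detect a degenerate simulated network distribution
#'
#' A simulated sample is flagged degenerate when (a) the mean simulated
#' simple-edge count falls below 2\% or above 98\% of the number of dyads,
#' (b) any per-term t-ratio |observed - simulated mean| / sd exceeds 4, or
#' (c) any simulated statistic has zero variance while its mean misses the
#' observed value.
#'
#' @param simStats matrix of simulated statistic vectors (columns named as
#'   the observed vector).
#' @param observed named observed statistic vector.
#' @param nVertices number of vertices (for the dyad count).
#' @return List with \code{degenerate} plus the individual condition flags
#'   and t-ratios.
#' @export
detectDegeneracy <- function(simStats, observed, nVertices) {
  stopifnot(nrow(simStats) >= 1)
  D <- nVertices * (nVertices - 1) / 2
  mu <- colMeans(simStats)
  sdev <- apply(simStats, 2, sd)
  tr <- ifelse(sdev > 0, abs(observed - mu) / sdev,
               ifelse(abs(observed - mu) < 1e-8, 0, Inf))
  eIdx <- match("edges", colnames(simStats))
  densityExtreme <- !is.na(eIdx) &&
    (mu[eIdx] < 0.02 * D || mu[eIdx] > 0.98 * D)
  tExtreme <- any(is.finite(tr) & tr > 4)
  frozen <- any(sdev == 0 & abs(observed - mu) > 1e-8)
  list(degenerate = densityExtreme || tExtreme || frozen,
       densityExtreme = densityExtreme, tExtreme = tExtreme,
       frozenStatistic = frozen, tRatios = tr,
       meanEdges = if (!is.na(eIdx)) mu[eIdx] else NA_real_, nDyads = D)
}

#' MCMC trace diagnostics
#'
#' Per-term trace summaries: mean and sd centered on the observed
#' statistic, lag-1 autocorrelation, and a Geweke-style comparison of the
#' first 10\% against the last 50\% of the trace.  A term warns when the
#' Geweke z exceeds 2 in absolute value or the centered mean is more than
#' half a simulated sd from zero.
#'
#' @param trace matrix of sampled statistics (one column per term).
#' @param observed named observed statistic vector.
#' @return List with a per-term data.frame (\code{table}) and an overall
#'   \code{pass} flag.
#' @export
mcmcDiagnostics <- function(trace, observed) {
  trace <- as.matrix(trace)
  if (nrow(trace) < 10) stop("trace must have at least 10 samples")
  m <- nrow(trace)
  i1 <- seq_len(max(2, floor(0.1 * m)))
  i2 <- seq(floor(0.5 * m) + 1, m)
  tab <- do.call(rbind, lapply(seq_len(ncol(trace)), function(k) {
    x <- trace[, k]
    sdev <- sd(x)
    lag1 <- if (sdev > 0) suppressWarnings(
      acf(x, lag.max = 1, plot = FALSE)$acf[2]) else NA_real_
    m1 <- mean(x[i1]); m2 <- mean(x[i2])
    v1 <- var(x[i1]); v2 <- var(x[i2])
    gz <- if (v1 + v2 > 0) (m1 - m2) / sqrt(v1 / length(i1) + v2 / length(i2))
          else 0
    centered <- mean(x) - observed[k]
    warnFlag <- (is.finite(gz) && abs(gz) > 2) ||
      (sdev > 0 && abs(centered) / sdev > 0.5)
    data.frame(term = colnames(trace)[k] %||% paste0("term", k),
               meanCentered = centered, sd = sdev, lag1 = lag1,
               gewekeZ = gz, status = if (warnFlag) "warn" else "pass",
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  list(table = tab, pass = all(tab$status == "pass"))
}

#' Fit the covariate and species-factor models with degeneracy fallback
#'
#' Fits the triad model (edges + gwesp(0.25, fixed) + nodecov(size) +
#' nodecov(count)) by Monte-Carlo maximum likelihood.  If that fit does
#' not converge or its simulated distribution is degenerate, the
#' covariate-only restriction (without the gwesp term, dyad-independent,
#' fitted exactly by maximum pseudolikelihood) replaces it and the bundle
#' is marked as a fallback.  The species-factor model (edges +
#' nodefactor(vertex.names), also dyad-independent) is fitted
#' independently and never falls back.  Goodness-of-fit reports with
#' \code{nSim} simulated networks are attached to both fits.  Degeneracy
#' never raises an error.
#'
#' @param network a \linkS4class{BenthicNetwork}; a single-vertex network
#'   yields a bundle with every fit marked not estimable.
#' @param control see \code{\link{ergmControl}}.
#' @param nSim simulated networks per goodness-of-fit report.
#' @param seed integer master seed; stage seeds are derived from it.
#' @return A \linkS4class{FitBundle}.
#' @export
fitWithFallback <- function(network, control = ergmControl(), nSim = 100,
                            seed = NULL) {
  stopifnot(is(network, "BenthicNetwork"))
  md <- list(surveyId = network@surveyId, site = network@site,
             depth = network@depth, aspect = network@aspect,
             nVertices = numVertices(network),
             nEdgesWeighted = edgeCount(network, weighted = TRUE),
             nEdgesSimple = edgeCount(network, weighted = FALSE),
             species = network@vertices$code)
  if (!isFittable(network)) {
    return(new("FitBundle", metadata = md, covariateFit = NULL,
               covariateModel = "none", fallback = FALSE,
               model2Fit = NULL, gofCovariate = NULL, gofModel2 = NULL,
               diagnostics = list(note = "single-vertex network: not estimable")))
  }
  sd0 <- seed %||% stableHash(network@surveyId, network@depth)
  fit1 <- mcmle(network, presetModel("model1"), control = control,
                seed = childSeed(sd0, "model1"))
  diagnostics <- list(model1Converged = isConverged(fit1),
                      model1Degenerate = isTRUE(fit1@flags$degenerate),
                      model1Summary = fit1@mcmcSummary)
  fallback <- !isConverged(fit1)
  if (fallback) {
    covFit <- mple(network, presetModel("model1A"))
    covModel <- "model1A"
  } else {
    covFit <- fit1
    covModel <- "model1"
  }
  m2 <- mple(network, presetModel("model2"))
  gofCov <- gof(covFit, network, nSim = nSim,
                seed = childSeed(sd0, "gof-cov"), control = control)
  gofM2 <- gof(m2, network, nSim = nSim,
               seed = childSeed(sd0, "gof-m2"), control = control)
  new("FitBundle", metadata = md, covariateFit = covFit,
      covariateModel = covModel, fallback = fallback, model2Fit = m2,
      gofCovariate = gofCov, gofModel2 = gofM2,
      diagnostics = diagnostics)
}
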