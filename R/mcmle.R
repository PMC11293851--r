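## Monte-Carlo maximum likelihood (Geyer-Thompson style): simulate at the
## current coefficients, re-weight to maximize the estimated likelihood
## ratio, repeat until the simulated statistic means match the observed
## statistics.

#' Monte-Carlo maximum likelihood estimation
#'
#' Initializes at the pseudolikelihood estimate, then iterates: simulate
#' \code{nSamples} networks at the current coefficients (chains restart at
#' the observed graph), check the per-term t-ratios |observed - simulated
#' mean| / simulated sd, and if any exceeds \code{tRatioTol} update the
#' coefficients by maximizing the importance-sampled log-likelihood ratio
#' (moves capped at \code{stepMax} per term).  Standard errors come from
#' the inverse covariance of the simulated statistics at the final
#' coefficients.  The log-likelihood is estimated by path sampling along
#' \eqn{t\hat\theta, t \in [0,1]} from the exactly known null
#' \eqn{\ell(0) = -D\log 2}.
#'
#' Degenerate simulated distributions (nearly empty or nearly complete
#' graphs, or statistics drifting many simulated standard deviations from
#' the observed values) never raise an error: the fit is returned with
#' \code{converged = FALSE} and its degeneracy flag set, and the caller
#' (see \code{\link{fitWithFallback}}) decides what to do.
#'
#' @param network a fittable \linkS4class{BenthicNetwork}.
#' @param model an \linkS4class{ErgmModel}.
#' @param control see \code{\link{ergmControl}}.
#' @param seed integer seed governing every simulation in the fit.
#' @return An \linkS4class{ErgmFit} with \code{method = "mcmle"}.
#' @export
mcmle <- function(network, model, control = ergmControl(), seed = NULL) {
  stopifnot(is(network, "BenthicNetwork"))
  if (!isFittable(network))
    stop("network is not fittable (fewer than 2 vertices)")
  withSeed(seed, mcmleImpl(network, model, control, seed))
}

mcmleImpl <- function(network, model, control, seed) {
  ex <- expandTerms(model, network@vertices)
  nm <- termNames(ex)
  p <- length(ex)
  A <- asAdjacency(network)
  n <- nrow(A)
  D <- n * (n - 1) / 2
  control <- resolveControl(control, D)
  g <- setNames(as.numeric(cpp_network_stats(A, ex)), nm)
  kinds <- vapply(ex, function(t) t$kind, 0L)
  edgeIdx <- which(kinds == 0L)[1]

  init <- mple(network, model)
  theta <- coef(init)
  if (init@flags$separation) {
    d <- min(max(sum(A) / 2 / D, 1 / (2 * D)), 1 - 1 / (2 * D))
    theta <- setNames(numeric(p), nm)
    if (!is.na(edgeIdx)) theta[edgeIdx] <- log(d / (1 - d))
  }
  theta[!is.finite(theta)] <- 0

  converged <- FALSE
  degenerate <- FALSE
  G <- NULL
  for (it in seq_len(control$maxIter)) {
    G <- mhSample(A, ex, theta, control$burnin, control$thin,
                  control$nSamples)$stats
    mu <- colMeans(G)
    sdev <- apply(G, 2, sd)
    tr <- ifelse(sdev > 0, (g - mu) / sdev,
                 ifelse(abs(g - mu) < 1e-8, 0, Inf))
    if (!is.na(edgeIdx)) {
      me <- mu[edgeIdx]
      if (me < 0.02 * D || me > 0.98 * D) { degenerate <- TRUE; break }
    }
    if (all(abs(tr) < control$tRatioTol)) { converged <- TRUE; break }
    ## maximize the importance-sampled log-likelihood ratio in delta
    Gc <- sweep(G, 2, g)   # rows: g_sim - g_obs
    negq <- function(delta) logSumExp(as.vector(Gc %*% delta)) - log(nrow(Gc))
    gradq <- function(delta) {
      lw <- as.vector(Gc %*% delta)
      w <- exp(lw - logSumExp(lw))
      as.vector(crossprod(Gc, w))
    }
    opt <- optim(numeric(p), negq, gradq, method = "BFGS",
                 control = list(maxit = 200))
    delta <- opt$par
    ## cap the move in standardized units (coefficient times statistic
    ## sd), so terms on large scales cannot trigger explosive updates
    sdSafe <- ifelse(sdev > 0, sdev, 1)
    mx <- max(abs(delta * sdSafe))
    if (mx > control$stepMax) delta <- delta * control$stepMax / mx
    theta <- theta + delta
  }

  mu <- colMeans(G)
  sdev <- apply(G, 2, sd)
  tr <- ifelse(sdev > 0, (g - mu) / sdev,
               ifelse(abs(g - mu) < 1e-8, 0, Inf))
  if (any(!is.finite(tr) | abs(tr) > 4)) degenerate <- TRUE
  mcmcSummary <- data.frame(term = nm, observed = g, simMean = mu,
                            simSd = sdev, tRatio = tr,
                            stringsAsFactors = FALSE, row.names = NULL)

  I <- stats::cov(G)
  se <- rep(NA_real_, p)
  ok <- diag(I) > 1e-10
  if (any(ok)) {
    V <- tryCatch(solve(I[ok, ok, drop = FALSE]), error = function(e) NULL)
    if (!is.null(V)) se[ok] <- sqrt(pmax(diag(V), 0))
  }

  ll <- NA_real_; logNorm <- NA_real_
  if (!degenerate) {
    lr <- pathLogNormalizer(A, ex, theta, D, control)
    logNorm <- lr
    ll <- -D * log(2) + sum(theta * g) - lr
  }
  fitObject(model = model, coef = setNames(theta, nm), se = se,
            logLik = ll, logNormalizer = logNorm, nDyads = D,
            converged = converged && !degenerate, method = "mcmle",
            mcmcSummary = mcmcSummary, seed = seed,
            flags = list(separation = init@flags$separation,
                         degenerate = degenerate))
}

## log k(theta) - log k(0) by path sampling: the derivative of l(t*theta)
## in t is theta' E_{t theta}[g]; integrate over a uniform grid by the
## trapezoid rule.  At t = 0 the expectation is exact: each dyad is an
## independent Bernoulli(1/2), so E[g] is computed directly.
pathLogNormalizer <- function(A, ex, theta, D, control) {
  B <- control$bridges
  ts <- seq(0, 1, length.out = B + 1)
  n <- nrow(A)
  derivs <- numeric(B + 1)
  derivs[1] <- sum(theta * nullExpectedStats(n, ex))
  thin <- max(1L, as.integer(ceiling(control$thin / 2)))
  for (b in 2:(B + 1)) {
    S <- mhSample(A, ex, ts[b] * theta, control$burnin, thin,
                  control$bridgeSamples)$stats
    derivs[b] <- sum(theta * colMeans(S))
  }
  sum((derivs[-1] + derivs[-(B + 1)]) / 2 * diff(ts))
}

## E[g] under theta = 0 (uniform over graphs; every dyad present w.p. 1/2).
nullExpectedStats <- function(n, ex) {
  D <- n * (n - 1) / 2
  vapply(ex, function(t) {
    if (t$kind == 0L) D / 2
    else if (t$kind == 2L) sum(t$x) * (n - 1) / 2
    else { # gwesp: E over edges; shared-partner count ~ Binomial(n-2, 1/4)
      tau <- t$decay
      k <- 0:(n - 2)
      pk <- stats::dbinom(k, n - 2, 0.25)
      w <- exp(tau) * (1 - (1 - exp(-tau))^k)
      D / 2 * sum(pk * w)
    }
  }, 0)
}
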