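#' @useDynLib benthicnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef glm.fit binomial optim median sd var cor cov
#'   quantile rgeom rgamma dbinom pnorm predict logLik setNames runif acf
#' @importFrom utils head read.csv write.csv
NULL

logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

## Evaluate `code` under a temporary RNG state seeded with `seed`; the
## caller's RNG stream is untouched.  seed = NULL runs code as-is.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

## Deterministic 31-bit string hash (order of named components matters).
stableHash <- function(...) {
  s <- paste(vapply(list(...), as.character, ""), collapse = "\r")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Derive a reproducible child seed from a master seed and a label
#'
#' Child seeds are stable hashes of the label combined with the master seed,
#' so regenerating one record of a campaign does not depend on the order in
#' which the other records were generated.
#'
#' @param master integer master seed.
#' @param ... label components (site, survey, depth, ...), coerced to
#'   character.
#' @return An integer seed in \[0, 2^31).
#' @export
childSeed <- function(master, ...) {
  as.integer((as.numeric(master) %% 2147483647 * 48271 +
                stableHash(...)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
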