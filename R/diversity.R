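## Cross-survey aggregation: species-factor effect tables, phylum
## summaries, per-site triad-coefficient profiles, and the co-occurrence
## social diversity proportions.

#' Pool species-factor effects across fitted networks
#'
#' Gathers each species' factor coefficient and z-value from every
#' network's species-factor fit.  A species' \code{n} is the number of
#' networks it occurs in; estimates exist only where the species is not
#' that network's (lexicographically first) reference vertex.  Species
#' occurring in no more than \code{minOccurrences} networks are excluded
#' from the reported table but kept in the raw output.
#'
#' @param bundles list of \linkS4class{FitBundle}s.
#' @param attrs optional species attribute table; adds a phylum column.
#' @param minOccurrences occurrence filter (report species with n >
#'   this).
#' @return A \linkS4class{SpeciesEffectTable}.
#' @export
collectSpeciesEffects <- function(bundles, attrs = NULL,
                                  minOccurrences = 5) {
  usable <- Filter(function(b) !is.null(model2Fit(b)), bundles)
  skipped <- length(bundles) - length(usable)
  if (!length(usable)) stop("no estimable model-2 fits")
  if (skipped) message(skipped, " bundle(s) without a model-2 fit skipped")

  raw <- list()
  occ <- list()
  for (b in usable) {
    fit <- model2Fit(b)
    sid <- bundleMetadata(b)$surveyId %||% "?"
    codes <- bundleMetadata(b)$species
    for (sp in codes) occ[[sp]] <- (occ[[sp]] %||% 0L) + 1L
    cf <- coef(fit); zv <- zValues(fit)
    pref <- "nodefactor.vertex.names."
    hit <- startsWith(names(cf), pref)
    sp <- substring(names(cf)[hit], nchar(pref) + 1L)
    for (k in seq_along(sp)) {
      z <- unname(zv[hit][k])
      raw[[sp[k]]] <- rbind(raw[[sp[k]]],
        data.frame(surveyId = sid, estimate = unname(cf[hit][k]),
                   z = z, sig = 2 * pnorm(-abs(z)),
                   stringsAsFactors = FALSE))
    }
  }
  allSpecies <- sort(names(occ))
  tab <- do.call(rbind, lapply(allSpecies, function(s) {
    est <- raw[[s]]$estimate %||% numeric(0)
    z <- raw[[s]]$z %||% numeric(0)
    z <- z[is.finite(z)]
    est <- est[is.finite(est)]
    data.frame(code = s, n = occ[[s]],
               medianZ = if (length(z)) median(z) else NA_real_,
               medianAbsZ = if (length(z)) median(abs(z)) else NA_real_,
               medianSig = if (length(z)) median(2 * pnorm(-abs(z)))
                           else NA_real_,
               meanZ = if (length(z)) mean(z) else NA_real_,
               meanSig = if (length(z)) mean(2 * pnorm(-abs(z)))
                         else NA_real_,
               meanCoef = if (length(est)) mean(est) else NA_real_,
               medianCoef = if (length(est)) median(est) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(attrs)) {
    m <- match(tab$code, attrs$code)
    tab$phylum <- ifelse(is.na(m), "unknown", attrs$phylum[m])
  }
  keep <- tab$n > minOccurrences & !is.na(tab$medianAbsZ)
  reported <- tab[keep, , drop = FALSE]
  rownames(reported) <- NULL
  new("SpeciesEffectTable", table = reported,
      raw = c(raw, sapply(setdiff(allSpecies, names(raw)),
                          function(s) NULL)),
      minOccurrences = minOccurrences)
}

#' Classify species' co-occurrence preferences
#'
#' A species is classed as forming consistent associations
#' ("preferential") when the median across its networks of the Wald
#' significance value \eqn{2\Phi(-|z|)} of its factor coefficient falls
#' below \code{zThreshold}: in more than half of the networks it occurs
#' in, its connectivity deviates significantly from the reference
#' species'.  Because the median commutes with the monotone map from
#' |z| to its significance value, this is exactly the conventional rule
#' median |z| > \eqn{\Phi^{-1}(1 - threshold/2)} (1.96 at the default
#' 0.05).  The sign of the median coefficient then splits "positive
#' homophily" from "negative/avoidance"; all other species are labelled
#' "none".  \code{rule = "median-z"} instead thresholds the median
#' absolute z-ratio itself at \code{zThreshold}, which singles out
#' species whose coefficients sit at the separation boundary
#' (enormous standard errors from attachment to every co-occurring
#' neighbour).
#'
#' @param table a \linkS4class{SpeciesEffectTable}.
#' @param zThreshold threshold on the median significance value.
#' @param rule \code{"significance"} (default) or \code{"median-z"}.
#' @return The table with \code{preferential} and \code{label} columns
#'   added.
#' @export
classifyPreferences <- function(table, zThreshold = 0.05,
                                rule = c("significance", "median-z")) {
  stopifnot(is(table, "SpeciesEffectTable"))
  rule <- match.arg(rule)
  tab <- table@table
  if (!nrow(tab)) stop("species effect table is empty")
  pref <- if (rule == "significance") tab$medianSig < zThreshold
          else tab$medianAbsZ < zThreshold
  pref[is.na(pref)] <- FALSE
  tab$preferential <- pref
  tab$label <- ifelse(!pref, "none",
                      ifelse(tab$medianCoef >= 0, "positive homophily",
                             "negative/avoidance"))
  new("SpeciesEffectTable", table = tab, raw = table@raw,
      minOccurrences = table@minOccurrences)
}

#' Aggregate species effects by phylum
#'
#' Unweighted means, over the species of each phylum, of the species-level
#' mean coefficient and mean z.  Species without a phylum assignment are
#' grouped under "unknown".
#'
#' @param table a \linkS4class{SpeciesEffectTable}.
#' @param attrs species attribute table providing phylum per code
#'   (optional if the table already carries a phylum column).
#' @return data.frame with columns phylum, meanCoef, meanZ, nSpecies.
#' @export
phylumAggregate <- function(table, attrs = NULL) {
  stopifnot(is(table, "SpeciesEffectTable"))
  tab <- table@table
  if (!"phylum" %in% names(tab)) {
    if (is.null(attrs)) stop("no phylum information supplied")
    m <- match(tab$code, attrs$code)
    tab$phylum <- ifelse(is.na(m), "unknown", attrs$phylum[m])
  }
  tab$phylum[is.na(tab$phylum) | !nzchar(tab$phylum)] <- "unknown"
  out <- do.call(rbind, lapply(split(tab, tab$phylum), function(s)
    data.frame(phylum = s$phylum[1],
               meanCoef = mean(s$meanCoef, na.rm = TRUE),
               meanZ = mean(s$meanZ, na.rm = TRUE),
               nSpecies = nrow(s), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

triadSupported <- function(b, gofPThreshold) {
  if (usedFallback(b) || b@covariateModel != "model1") return(FALSE)
  fit <- covariateFit(b)
  if (is.null(fit) || !isConverged(fit)) return(FALSE)
  gs <- gofTable(b@gofCovariate)
  pe <- gs$p[gs$term == "edges"]
  pg <- gs$p[startsWith(gs$term, "gwesp")]
  length(pe) == 1 && length(pg) == 1 && pe > gofPThreshold &&
    pg > gofPThreshold
}

#' Co-occurrence social diversity proportions
#'
#' A network counts as showing co-occurrence social diversity when its
#' covariate model is the full triad model (no fallback), the fit
#' converged, and both the edges and gwesp goodness-of-fit p-values exceed
#' \code{gofPThreshold} — i.e. dyad and triad formation reproduce the
#' observed structure.  Species proportions come from a classified
#' species-effect table: the loose count is every species labelled
#' preferential; the strict count further requires a median significance
#' value at most 0.01 with a positive median coefficient.
#'
#' @param bundles list of \linkS4class{FitBundle}s.
#' @param speciesTable a classified \linkS4class{SpeciesEffectTable}
#'   (optional).
#' @param gofPThreshold threshold for the GoF p-values.
#' @return List: nNetworks, nTriadSupported, proportion, and (when a
#'   species table is supplied) nSpeciesTotal, nSpeciesPreferential,
#'   proportionSpeciesPreferential, nSpeciesStrict, plus the per-site
#'   gwesp summaries.
#' @export
diversityProportions <- function(bundles, speciesTable = NULL,
                                 gofPThreshold = 0.05) {
  stopifnot(length(bundles) >= 1)
  supported <- vapply(bundles, triadSupported, TRUE,
                      gofPThreshold = gofPThreshold)
  out <- list(nNetworks = length(bundles),
              nTriadSupported = sum(supported),
              proportion = sum(supported) / length(bundles))
  if (!is.null(speciesTable)) {
    stopifnot(is(speciesTable, "SpeciesEffectTable"))
    tab <- speciesTable@table
    if (!"preferential" %in% names(tab))
      stop("speciesTable must be classified first (classifyPreferences)")
    nTotal <- length(speciesTable@raw)
    out$nSpeciesTotal <- nTotal
    out$nSpeciesPreferential <- sum(tab$preferential)
    out$proportionSpeciesPreferential <-
      if (nTotal) sum(tab$preferential) / nTotal else 0
    out$nSpeciesStrict <- sum(tab$preferential & tab$medianSig <= 0.01 &
                                tab$medianCoef > 0, na.rm = TRUE)
  }
  haveModel1 <- any(vapply(bundles, function(b)
    b@covariateModel == "model1", TRUE))
  if (haveModel1) out$siteGwesp <- siteGwespSummary(bundles)
  out
}

#' Per-site gwesp coefficient profiles
#'
#' Collects the fitted gwesp coefficients of every non-fallback triad
#' model fit, grouped by site across depths and aspects.  A positive
#' median indicates a site whose networks need triad formation to be
#' reproduced; sites with only fallback fits are reported with an empty
#' coefficient list.
#'
#' @param bundles list of \linkS4class{FitBundle}s.
#' @return List with \code{summary} (data.frame: site, n, medianCoef,
#'   nPositive, nNegative) and \code{coefficients} (named list of
#'   coefficient vectors).
#' @export
siteGwespSummary <- function(bundles) {
  hasM1 <- vapply(bundles, function(b) b@covariateModel == "model1", TRUE)
  if (!any(hasM1)) stop("no model-1 fits among the bundles")
  sites <- vapply(bundles, function(b)
    as.character(bundleMetadata(b)$site %||% "?"), "")
  coefs <- lapply(split(seq_along(bundles), sites), function(idx) {
    out <- numeric(0)
    for (b in bundles[idx]) {
      if (b@covariateModel != "model1") next
      cf <- coef(covariateFit(b))
      gw <- cf[startsWith(names(cf), "gwesp")]
      if (length(gw)) out <- c(out, unname(gw))
    }
    out
  })
  summary <- do.call(rbind, lapply(names(coefs), function(s)
    data.frame(site = s, n = length(coefs[[s]]),
               medianCoef = if (length(coefs[[s]]))
                 median(coefs[[s]]) else NA_real_,
               nPositive = sum(coefs[[s]] > 0),
               nNegative = sum(coefs[[s]] < 0),
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL
  list(summary = summary, coefficients = coefs)
}
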