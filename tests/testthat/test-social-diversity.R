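## Hand-built bundles let the aggregation logic be tested without any
## model fitting.

stubFit <- function(codes, est, z, formulaStr = "edges + nodefactor(vertex.names)") {
  nm <- c("edges", paste0("nodefactor.vertex.names.", codes[-1]))
  coefs <- setNames(c(-1, est), nm)
  se <- ifelse(z == 0, Inf, est / z)
  ses <- setNames(c(0.5, abs(se)), nm)
  fit <- benthicnet:::fitObject(
    model = ergmModel(formulaStr), coef = coefs, se = ses,
    logLik = -10, logNormalizer = 0, nDyads = 10, converged = TRUE,
    method = "mple")
  fit@z <- setNames(c(-2, z), nm)
  fit
}

stubGof <- function(terms, p) {
  new("GofReport",
      stats = data.frame(term = terms, observed = 1, simMean = 1,
                         simSd = 1, p = p, stringsAsFactors = FALSE),
      degree = list(), esp = list(), nSim = 100L, seed = 1L)
}

stubBundle <- function(codes, est, z, site = "S1", surveyId = "S1.1",
                       covModel = "model1", gwespCoef = 0.5,
                       pEdges = 0.9, pGwesp = 0.9, converged = TRUE) {
  m1 <- benthicnet:::fitObject(
    model = presetModel(if (covModel == "model1") "model1" else "model1A"),
    coef = if (covModel == "model1")
      c(edges = -1, gwesp.fixed.0.25 = gwespCoef, nodecov.size = 0,
        nodecov.count = 0)
    else c(edges = -1, nodecov.size = 0, nodecov.count = 0),
    se = rep(0.5, if (covModel == "model1") 4 else 3),
    logLik = -20, logNormalizer = 0, nDyads = 10, converged = converged,
    method = if (covModel == "model1") "mcmle" else "mple")
  gofTerms <- names(coef(m1))
  new("FitBundle",
      metadata = list(surveyId = surveyId, site = site, depth = 2,
                      aspect = "photophilous", nVertices = length(codes),
                      nEdgesWeighted = 20L, nEdgesSimple = 10L,
                      species = codes),
      covariateFit = m1, covariateModel = covModel,
      fallback = covModel == "model1A",
      model2Fit = stubFit(codes, est, z),
      gofCovariate = stubGof(gofTerms, c(pEdges, pGwesp,
                                         rep(0.9, length(gofTerms) - 2))),
      gofModel2 = NULL, diagnostics = list())
}

test_that("species effects pool estimates and apply the occurrence filter", {
  codes <- c("A", "B", "C")
  bundles <- lapply(1:7, function(k)
    stubBundle(codes, est = c(2, -1), z = c(3, -0.5),
               surveyId = paste0("S", k)))
  ## species D appears in only 3 networks
  bundles <- c(bundles, lapply(1:3, function(k)
    stubBundle(c("A", "B", "D"), est = c(1, 0.2), z = c(1, 0.1),
               surveyId = paste0("T", k))))
  se <- collectSpeciesEffects(bundles, minOccurrences = 5)
  tab <- effectTable(se)
  expect_false("D" %in% tab$code)        # filtered (n = 3 <= 5)
  expect_true("D" %in% names(se@raw))    # kept in the raw output
  expect_equal(tab$n[tab$code == "B"], 10)
  expect_equal(tab$medianZ[tab$code == "B"], 3)
  ## A is always the reference: occurrences counted, no estimates
  expect_equal(tab$code, c("B", "C"))
  expect_error(collectSpeciesEffects(list()), "no estimable")
})

test_that("classification splits homophily, avoidance and none", {
  codes <- c("A", "B", "C", "D")
  bundles <- lapply(1:8, function(k)
    stubBundle(codes, est = c(2.5, -2.5, 0.3), z = c(4, -4, 0.4),
               surveyId = paste0("S", k)))
  cls <- classifyPreferences(collectSpeciesEffects(bundles))
  tab <- effectTable(cls)
  expect_equal(tab$label[tab$code == "B"], "positive homophily")
  expect_equal(tab$label[tab$code == "C"], "negative/avoidance")
  expect_equal(tab$label[tab$code == "D"], "none")
  ## significance rule: median sig < 0.05  <=>  median |z| > 1.96
  expect_true(all(tab$preferential == (tab$medianAbsZ > 1.96)))

  ## the separation-boundary rule flags near-zero z instead
  bundles2 <- lapply(1:8, function(k)
    stubBundle(codes, est = c(20, -1, 0.3), z = c(0.001, -1, 0.4),
               surveyId = paste0("S", k)))
  cls2 <- classifyPreferences(collectSpeciesEffects(bundles2),
                              rule = "median-z")
  tab2 <- effectTable(cls2)
  expect_equal(tab2$label[tab2$code == "B"], "positive homophily")
  expect_equal(tab2$label[tab2$code == "C"], "none")
})

test_that("phylum aggregation averages species-level means", {
  codes <- c("A", "B", "C")
  bundles <- lapply(1:8, function(k)
    stubBundle(codes, est = c(-2, -6), z = c(-1, -2),
               surveyId = paste0("S", k)))
  attrs <- data.frame(code = c("B", "C"), name = c("b", "c"),
                      phylum = c("P", "P"), category = NA)
  se <- collectSpeciesEffects(bundles, attrs = attrs)
  ph <- phylumAggregate(se)
  expect_equal(ph$meanCoef[ph$phylum == "P"], -4)
  expect_equal(ph$nSpecies[ph$phylum == "P"], 2)

  seU <- collectSpeciesEffects(bundles)
  phU <- phylumAggregate(seU, attrs = data.frame(code = character(),
                                                 phylum = character()))
  expect_equal(phU$phylum, "unknown")
})

test_that("diversity proportions count qualifying networks", {
  codes <- c("A", "B", "C")
  good <- lapply(1:68, function(k)
    stubBundle(codes, est = c(1, -1), z = c(2.5, -0.5),
               surveyId = paste0("G", k)))
  badGof <- lapply(1:10, function(k)
    stubBundle(codes, est = c(1, -1), z = c(2.5, -0.5), pGwesp = 0.01,
               surveyId = paste0("B", k)))
  fallen <- lapply(1:7, function(k)
    stubBundle(codes, est = c(1, -1), z = c(2.5, -0.5),
               covModel = "model1A", surveyId = paste0("F", k)))
  bundles <- c(good, badGof, fallen)
  cls <- classifyPreferences(collectSpeciesEffects(bundles))
  dp <- diversityProportions(bundles, cls)
  expect_equal(dp$nNetworks, 85)
  expect_equal(dp$nTriadSupported, 68)
  expect_equal(dp$proportion, 0.8)
  expect_equal(dp$nSpeciesTotal, 3)
  expect_equal(dp$nSpeciesPreferential, 1)
  expect_true(dp$proportion >= 0 && dp$proportion <= 1)

  ## all-fallback: proportion 0
  dp0 <- diversityProportions(fallen)
  expect_equal(dp0$proportion, 0)
})

test_that("aggregation is invariant to bundle order", {
  codes <- c("A", "B", "C")
  bundles <- lapply(1:10, function(k)
    stubBundle(codes, est = c(k / 5, -1), z = c(k / 3, -0.5),
               surveyId = paste0("S", k),
               site = c("X", "Y")[1 + k %% 2]))
  t1 <- effectTable(collectSpeciesEffects(bundles))
  t2 <- effectTable(collectSpeciesEffects(rev(bundles)))
  expect_equal(t1, t2)
  s1 <- siteGwespSummary(bundles)$summary
  s2 <- siteGwespSummary(rev(bundles))$summary
  expect_equal(s1, s2)
})

test_that("site gwesp summaries group coefficients by site", {
  codes <- c("A", "B", "C")
  bundles <- c(
    lapply(1:4, function(k) stubBundle(codes, c(1, -1), c(1, -1),
                                       site = "hi", gwespCoef = 1 + k / 10,
                                       surveyId = paste0("H", k))),
    lapply(1:4, function(k) stubBundle(codes, c(1, -1), c(1, -1),
                                       site = "lo", gwespCoef = -0.5 - k / 10,
                                       surveyId = paste0("L", k))),
    list(stubBundle(codes, c(1, -1), c(1, -1), site = "fb",
                    covModel = "model1A", surveyId = "FB")))
  s <- siteGwespSummary(bundles)
  tab <- s$summary
  expect_gt(tab$medianCoef[tab$site == "hi"], 0)
  expect_lt(tab$medianCoef[tab$site == "lo"], 0)
  ## fallback-only site present with an empty coefficient list
  expect_equal(tab$n[tab$site == "fb"], 0)
  expect_true(is.na(tab$medianCoef[tab$site == "fb"]))
  expect_length(s$coefficients[["hi"]], 4)
  expect_error(siteGwespSummary(list(stubBundle(codes, c(1, 1), c(1, 1),
                                                covModel = "model1A"))),
               "no model-1")
})

test_that("bundle tables flatten to one row per term", {
  b <- stubBundle(c("A", "B", "C"), est = c(1, -1), z = c(2, -1))
  tab <- bundleTable(list(b))
  expect_true(all(c("estimate", "se", "z", "gofP", "fallback") %in%
                    names(tab)))
  expect_equal(sum(tab$model == "model1"), 4)
  expect_equal(sum(tab$model == "model2"), 3)
  f <- withr::local_tempfile(fileext = ".json")
  writeFitJson(b, f)
  js <- jsonlite::read_json(f)
  expect_equal(js$covariateModel, "model1")
  expect_length(js$covariateFit$estimate, 4)
})
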