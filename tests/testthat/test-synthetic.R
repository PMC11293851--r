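test_that("community construction is deterministic and plants pairs", {
  m1 <- makeCommunity(5, list(c(1, 2, 10)), seed = 1)
  m2 <- makeCommunity(5, list(c(1, 2, 10)), seed = 1)
  expect_equal(m1@abundance, m2@abundance)
  expect_equal(m1@affinity[1, 2], 10)
  expect_equal(m1@affinity[2, 1], 10)
  expect_equal(sum(m1@affinity != 1), 2)
  expect_equal(sum(m1@abundance), 1)

  mN <- makeCommunity(5, seed = 2)
  expect_true(all(mN@affinity == 1))
  expect_error(makeCommunity(5, list(c(1, 9, 10))), "out of range")
  expect_error(makeCommunity(5, list(c(1, 2, -1))), "> 0")
})

test_that("simulated transects satisfy the structural invariants", {
  m <- makeCommunity(8, seed = 3, triadProp = 0.2)
  for (s in 1:5) {
    tr <- simulateTransect(m, seed = s)
    expect_equal(transectLength(tr), 500)
    runs <- runLengthEncode(tr)
    expect_true(all(runs$species[-1] != runs$species[-nrow(runs)]))
    expect_equal(sum(runs$length), 500)
    net <- buildNetwork(runs, nonSpecies = character())
    expect_equal(edgeCount(net, weighted = TRUE), nrow(runs) - 1L)
  }
  expect_identical(speciesCodes(simulateTransect(m, seed = 9)),
                   speciesCodes(simulateTransect(m, seed = 9)))
})

test_that("two species alternate strictly into a single edge", {
  m <- makeCommunity(2, seed = 1)
  tr <- simulateTransect(m, seed = 4)
  runs <- runLengthEncode(tr)
  expect_true(all(runs$species[-1] != runs$species[-nrow(runs)]))
  net <- buildNetwork(runs, nonSpecies = character())
  expect_equal(edgeCount(net, weighted = FALSE), 1L)
})

test_that("neutral next-species draws follow relative abundances", {
  ## with phi = 1 and triadProp = 0 the successor of a fixed species is
  ## multinomial over the others proportional to abundance
  m <- makeCommunity(6, seed = 5)
  ab <- m@abundance
  counts <- withr::with_seed(99, {
    draws <- table(factor(replicate(10000, {
      w <- ab; w[3] <- 0
      sample.int(6, 1, prob = w)
    }), levels = 1:6))
    as.vector(draws)
  })
  expected <- ab; expected[3] <- 0; expected <- expected / sum(expected)
  chi <- suppressWarnings(chisq.test(counts[-3], p = expected[-3]))
  expect_gt(chi$p.value, 0.001)

  ## the same law drives the generator: successors of runs of species k
  trs <- lapply(1:12, function(s) simulateTransect(m, seed = 200 + s))
  nxt <- unlist(lapply(trs, function(tr) {
    runs <- runLengthEncode(tr)
    sp <- runs$species
    nxt <- sp[-1][sp[-nrow(runs)] == m@species[3]]
  }))
  obs <- table(factor(nxt, levels = m@species[-3]))
  chi2 <- suppressWarnings(chisq.test(as.vector(obs), p = expected[-3]))
  expect_gt(chi2$p.value, 0.001)
})

test_that("planted affinity inflates pair adjacency above the neutral rate", {
  neutral <- makeCommunity(8, seed = 6)
  planted <- makeCommunity(8, list(c(1, 2, 50)), seed = 6)
  pairMult <- function(m, seed) {
    net <- buildNetwork(runLengthEncode(simulateTransect(m, seed = seed)),
                        nonSpecies = character())
    e <- edgeTable(net)
    hit <- e$u == "S01" & e$v == "S02"
    if (any(hit)) e$multiplicity[hit] else 0L
  }
  wins <- sapply(1:20, function(s)
    pairMult(planted, s) > pairMult(neutral, s))
  expect_gte(mean(wins), 0.95)
})

test_that("triad propensity shifts the fitted gwesp coefficient upward", {
  ## campaign-scale communities; compare converged triad-model fits
  gwespAt <- function(tp) {
    m <- makeCommunity(20, seed = 11, abundanceShape = 4, triadProp = tp,
                       runLengthMean = 2.6, transectLength = 500)
    coefs <- sapply(1:8, function(s) {
      net <- buildNetwork(runLengthEncode(simulateTransect(m, seed = 30 + s)),
                          nonSpecies = character())
      f <- mcmle(net, presetModel("model1"),
                 ergmControl(nSamples = 600, maxIter = 30), seed = s)
      if (isConverged(f) && !fitFlags(f)$separation)
        unname(coef(f)[2]) else NA_real_
    })
    coefs[!is.na(coefs)]
  }
  neutral <- gwespAt(0)
  triadic <- gwespAt(0.45)
  expect_lt(median(neutral), median(triadic))
  ## neutral communities centre near zero
  expect_lt(abs(median(neutral)), 1.2)
})

test_that("campaigns follow the survey design and master seed", {
  camp <- simulateCampaign(seed = 7)
  expect_length(camp$records, 85)
  expect_equal(length(unique(vapply(camp$records, surveySite, ""))), 8)
  expect_equal(sort(unique(vapply(camp$records, surveyDepth, 0))),
               c(2, 4, 7, 14, 23))
  camp2 <- simulateCampaign(seed = 7)
  expect_identical(lapply(camp$records, speciesCodes),
                   lapply(camp2$records, speciesCodes))

  one <- simulateCampaign(campaignDesign(
    sites = data.frame(site = "X", surveyId = "X.1",
                       aspect = "photophilous"),
    depths = 2, siteTriadProp = c(X = 0)), seed = 1)
  expect_length(one$records, 1)
})

test_that("campaign truth identifies the planted associates", {
  camp <- simulateCampaign(seed = 3)
  truth <- camp$truth
  expect_length(truth$plantedSpecies, 3)
  ## associates are, by design, common species
  ab <- truth$community@abundance
  idx <- match(truth$plantedSpecies, truth$community@species)
  expect_true(all(rank(-ab)[idx] <= 5))
  ## every planted species takes part in many planted pairs
  members <- c(truth$plantedPairs$a, truth$plantedPairs$b)
  expect_true(all(table(members)[truth$plantedSpecies] > 10))
})

test_that("recovery scoring is exact on the truth itself", {
  camp <- simulateCampaign(seed = 2)
  rec <- scoreRecovery(camp$truth,
                       preferentialSpecies = camp$truth$plantedSpecies)
  expect_equal(rec$sensitivity, 1)
  expect_equal(rec$specificity, 1)
  expect_error(scoreRecovery(camp$truth, preferentialSpecies = "ZZZ"),
               "unknown species")
})

test_that("campaigns write the CSV formats the parser consumes", {
  dir <- withr::local_tempdir()
  camp <- simulateCampaign(campaignDesign(
    sites = data.frame(site = "X", surveyId = "X.1",
                       aspect = "photophilous"),
    depths = c(2, 4), siteTriadProp = c(X = 0.2), nSpecies = 6), seed = 5)
  writeCampaign(camp, dir)
  recs <- parseTransectTable(file.path(dir, "transects.csv"))
  expect_length(recs, 2)
  expect_identical(speciesCodes(recs[[1]]), speciesCodes(camp$records[[1]]))
  attrs <- readSpeciesAttributes(file.path(dir, "species.csv"))
  expect_equal(attrs$code, camp$truth$community@species)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(unlist(truth$plantedSpecies), camp$truth$plantedSpecies)
})

test_that("child seeds are stable and order-independent", {
  expect_identical(childSeed(5, "A", "B", 2), childSeed(5, "A", "B", 2))
  expect_false(childSeed(5, "A", "B", 2) == childSeed(5, "B", "A", 2))
  expect_true(childSeed(2147483646, paste(rep("x", 100), collapse = "")) <
                2^31)
})
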