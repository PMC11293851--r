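test_that("transect tables parse into one record per survey-depth", {
  recs <- lapply(1:3, function(k)
    transectRecord(paste0("S", k), "siteA", c(2, 4, 7)[k], "photophilous",
                   rep(c("A", "B"), each = 5)))
  f <- withr::local_tempfile(fileext = ".csv")
  writeTransectCsv(recs, f)
  parsed <- parseTransectTable(f)
  expect_length(parsed, 3)
  expect_equal(surveyId(parsed[[1]]), "S1")
  expect_equal(speciesCodes(parsed[[2]]), rep(c("A", "B"), each = 5))
  expect_equal(surveyDepth(parsed[[3]]), 7)
})

test_that("a 17-survey, five-depth design yields 85 records of 500 points", {
  surveys <- sprintf("SV%02d", 1:17)
  depths <- c(2, 4, 7, 14, 23)
  recs <- unlist(lapply(surveys, function(s) lapply(depths, function(d)
    transectRecord(s, substr(s, 1, 4), d, "photophilous",
                   rep(c("A", "B", "C", "D"), length.out = 500)))),
    recursive = FALSE)
  f <- withr::local_tempfile(fileext = ".csv")
  writeTransectCsv(recs, f)
  parsed <- parseTransectTable(f)
  expect_length(parsed, 85)
  expect_true(all(vapply(parsed, transectLength, 0L) == 500))
  ## 5 m at 1 cm resolution = 500 observation units
  expect_identical(500 / 100 * 100, 500)
})

test_that("position gaps, duplicates, and missing columns are reported", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(survey_id = "T1", site = "A", depth_m = 2,
                   aspect = "photophilous", position_cm = c(1, 2, 4),
                   species_code = c("A", "A", "B"))
  write.csv(df, f, row.names = FALSE)
  expect_error(parseTransectTable(f), "missing position 3")

  df$position_cm <- c(1, 2, 2)
  write.csv(df, f, row.names = FALSE)
  expect_error(parseTransectTable(f), "duplicate position 2")

  write.csv(df[, -6], f, row.names = FALSE)
  expect_error(parseTransectTable(f), "species_code")

  write.csv(df[0, ], f, row.names = FALSE)
  expect_error(parseTransectTable(f), "empty")
})

test_that("column mappings can rename inputs", {
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(tid = "T1", loc = "A", z = 2, asp = "sciaphilous",
                       cm = 1:4, sp = c("A", "A", "B", "B")),
            f, row.names = FALSE)
  recs <- parseTransectTable(f, columns = c(survey_id = "tid", site = "loc",
                                            depth = "z", aspect = "asp",
                                            position = "cm", species = "sp"))
  expect_equal(speciesCodes(recs[[1]]), c("A", "A", "B", "B"))
  expect_error(parseTransectTable(f, columns = c(bogus = "x")),
               "unknown column")
})

test_that("run-length encoding reproduces maximal runs", {
  r <- runLengthEncode(toyRecord("AAAAABBBBCCAA"))
  expect_equal(r$species, c("A", "B", "C", "A"))
  expect_equal(r$start, c(1L, 6L, 10L, 12L))
  expect_equal(r$length, c(5L, 4L, 2L, 2L))

  r1 <- runLengthEncode(toyRecord("AAAA"))
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$length, 4L)
})

test_that("run-length encoding round-trips random transects", {
  set.seed(41)
  for (rep in 1:20) {
    s <- paste(sample(LETTERS[1:5], 200, replace = TRUE), collapse = "")
    runs <- runLengthEncode(toyRecord(s))
    ## maximality: consecutive runs always change species
    expect_true(all(runs$species[-1] != runs$species[-nrow(runs)]))
    ## concatenation reproduces the input exactly
    rebuilt <- paste(rep(runs$species, runs$length), collapse = "")
    expect_identical(rebuilt, s)
    expect_equal(sum(runs$length), nchar(s))
  }
})

test_that("the worked transect builds the expected network", {
  net <- netFromString("AAAAABBBBCCAA")
  v <- vertexTable(net)
  expect_equal(v$code, c("A", "B", "C"))
  expect_equal(v$size, c(7, 4, 2))
  expect_equal(v$count, c(2L, 1L, 1L))
  e <- edgeTable(net)
  expect_equal(paste(e$u, e$v), c("A B", "A C", "B C"))
  expect_equal(e$multiplicity, rep(1L, 3))
  expect_equal(edgeCount(net, weighted = TRUE), 3L)
})

test_that("adjacency multiplicities accumulate and conserve totals", {
  net <- netFromString("ABAB")
  expect_equal(vertexTable(net)$size, c(2, 2))
  expect_equal(vertexTable(net)$count, c(2L, 2L))
  expect_equal(edgeTable(net)$multiplicity, 3L)

  set.seed(7)
  for (rep in 1:10) {
    s <- paste(sample(LETTERS[1:6], 500, replace = TRUE), collapse = "")
    runs <- runLengthEncode(toyRecord(s))
    net <- buildNetwork(runs, nonSpecies = character())
    v <- vertexTable(net)
    expect_equal(sum(v$size), 500)
    expect_equal(sum(v$count), nrow(runs))
    ## linear transect: weighted edges = runs - 1
    expect_equal(edgeCount(net, weighted = TRUE), nrow(runs) - 1L)
    ## no self-loops, bounded simple-edge count
    expect_true(all(edgeTable(net)$u != edgeTable(net)$v))
    n <- nrow(v)
    expect_lte(edgeCount(net, weighted = FALSE), n * (n - 1) / 2)
  }
})

test_that("run order matters: shuffled runs change the network", {
  runs <- runLengthEncode(toyRecord("AABBCCAABBCCDD"))
  net <- buildNetwork(runs)
  shuffled <- runs[c(1, 3, 2, 4, 6, 5, 7), ]  # still alternating species
  net2 <- buildNetwork(shuffled)
  expect_false(identical(edgeTable(net), edgeTable(net2)))
})

test_that("non-species codes break adjacency instead of bridging it", {
  net <- buildNetwork(runLengthEncode(toyRecord("AABAREABB", id = "T")),
                      nonSpecies = character())
  ## with an empty non-species set every token is a vertex
  expect_true("R" %in% vertexTable(net)$code)

  rec <- transectRecord("T", "s", 2, "unknown",
                        c("A", "A", "BARE", "B", "B", "A"))
  net2 <- buildNetwork(runLengthEncode(rec))
  expect_equal(vertexTable(net2)$code, c("A", "B"))
  e <- edgeTable(net2)
  ## A|BARE|B: the A-B boundary is a substrate gap, only B-A remains
  expect_equal(sum(e$multiplicity), 1L)
  expect_equal(sum(vertexTable(net2)$size), 5)
})

test_that("single-species transects are flagged not fittable", {
  net <- netFromString("AAAAAA")
  expect_equal(numVertices(net), 1L)
  expect_equal(edgeCount(net), 0L)
  expect_false(isFittable(net))
})

test_that("networks round-trip through GraphML and edge CSVs", {
  net <- buildNetwork(runLengthEncode(toyRecord("AAAAABBBBCCAABB")),
                      attrs = data.frame(code = c("A", "B"),
                                         name = c("a", "b"),
                                         phylum = c("Porifera", "Rhodophyta"),
                                         category = NA),
                      surveyId = "T1", site = "siteA", depth = 7,
                      aspect = "photophilous")
  g <- withr::local_tempfile(fileext = ".graphml")
  writeNetwork(net, g, format = "graphml")
  back <- readNetwork(g, format = "graphml")
  expect_equal(vertexTable(back), vertexTable(net))
  expect_equal(edgeTable(back), edgeTable(net))
  expect_equal(surveyId(back), "T1")
  expect_equal(surveyDepth(back), 7)

  b <- withr::local_tempfile()
  writeNetwork(net, b, format = "edge-csv")
  back2 <- readNetwork(b, format = "edge-csv")
  expect_equal(vertexTable(back2), vertexTable(net))
  expect_equal(edgeTable(back2), edgeTable(net))
  expect_equal(surveyAspect(back2), "photophilous")
})

test_that("malformed network files are rejected", {
  net <- netFromString("AABB")
  b <- withr::local_tempfile()
  writeNetwork(net, b, format = "edge-csv")
  e <- read.csv(paste0(b, "_edges.csv"))
  e$multiplicity <- 0L
  write.csv(e, paste0(b, "_edges.csv"), row.names = FALSE)
  expect_error(readNetwork(b, format = "edge-csv"), "multiplicity")
  expect_error(readNetwork("nope.graphml", "graphml"), "not found")
  expect_error(writeNetwork(net, "x", format = "bogus"))
})
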