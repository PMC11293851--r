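## Shared fixtures: small hand-built networks and transect tables.

codesOf <- function(s) strsplit(s, "")[[1]]

toyRecord <- function(s = "AAAAABBBBCCAA", id = "T1", site = "siteA",
                      depth = 7, aspect = "photophilous") {
  transectRecord(id, site, depth, aspect, codesOf(s))
}

## network from a plain string transect
netFromString <- function(s, ...) {
  buildNetwork(runLengthEncode(toyRecord(s)), ...)
}

## network from an explicit vertex set and edge list (size/count default 1)
makeNet <- function(codes, edges = NULL, size = NULL, count = NULL,
                    phylum = NULL, ...) {
  v <- data.frame(code = codes,
                  size = size %||% rep(1, length(codes)),
                  count = count %||% rep(1L, length(codes)),
                  phylum = phylum %||% rep("unknown", length(codes)),
                  stringsAsFactors = FALSE)
  e <- if (is.null(edges) || !nrow(edges))
    data.frame(u = character(), v = character(), multiplicity = integer())
  else data.frame(u = pmin(edges[, 1], edges[, 2]),
                  v = pmax(edges[, 1], edges[, 2]),
                  multiplicity = if (ncol(edges) > 2)
                    as.integer(edges[, 3]) else 1L,
                  stringsAsFactors = FALSE)
  md <- list(surveyId = "T", site = "s", depth = 2, aspect = "unknown")
  md[names(list(...))] <- list(...)
  new("BenthicNetwork", vertices = v, edges = e,
      surveyId = md$surveyId, site = md$site, depth = md$depth,
      aspect = md$aspect)
}

## network from a 0/1 adjacency matrix
netFromAdj <- function(A, codes = NULL, size = NULL, count = NULL) {
  n <- nrow(A)
  codes <- codes %||% sprintf("V%02d", seq_len(n))
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  e <- if (nrow(idx))
    data.frame(u = codes[idx[, 1]], v = codes[idx[, 2]],
               multiplicity = 1L, stringsAsFactors = FALSE)
  else NULL
  makeNet(codes, e, size = size, count = count)
}

randomAdj <- function(n, p = 0.5) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- rbinom(length(up), 1, p)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

completeAdj <- function(n) {
  A <- matrix(1L, n, n); diag(A) <- 0L; A
}

## transect CSV on disk from a set of records
writeTransectCsv <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(r)
    data.frame(survey_id = surveyId(r), site = surveySite(r),
               depth_m = surveyDepth(r), aspect = surveyAspect(r),
               position_cm = seq_len(transectLength(r)),
               species_code = speciesCodes(r), stringsAsFactors = FALSE)))
  write.csv(rows, path, row.names = FALSE)
  path
}

## brute-force gwesp from the defining sum over edges' shared partners
bruteGwesp <- function(A, tau) {
  n <- nrow(A)
  total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!A[i, j]) next
    cn <- sum(A[i, ] & A[j, ])
    total <- total + exp(tau) * (1 - (1 - exp(-tau))^cn)
  }
  total
}

## independent exhaustive enumerator over all graphs on n vertices,
## statistics computed via igraph (second route, used as the exact-MLE
## oracle's oracle)
enumerateStatsIgraph <- function(n, tau, size = NULL) {
  D <- n * (n - 1) / 2
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  out <- matrix(0, 2^D, if (is.null(size)) 2 else 3)
  for (m in 0:(2^D - 1)) {
    bits <- as.integer(intToBits(m))[seq_len(D)]
    A <- matrix(0L, n, n)
    on <- which(bits == 1)
    for (k in on) {
      A[pairs[k, 1], pairs[k, 2]] <- 1L
      A[pairs[k, 2], pairs[k, 1]] <- 1L
    }
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    stats <- c(igraph::ecount(g), bruteGwesp(A, tau))
    if (!is.null(size)) {
      el <- igraph::as_edgelist(g, names = FALSE)
      stats <- c(stats, if (nrow(el)) sum(size[el[, 1]] + size[el[, 2]])
                 else 0)
    }
    out[m + 1, ] <- stats
  }
  out
}

## tiny campaign design for pipeline tests (kept small for speed)
smallDesign <- function(...) {
  sites <- data.frame(site = c("A", "A", "B", "B"),
                      surveyId = c("A.1", "A.2", "B.1", "B.2"),
                      aspect = c("photophilous", "sciaphilous",
                                 "photophilous", "sciaphilous"),
                      stringsAsFactors = FALSE)
  campaignDesign(sites = sites, depths = c(2, 14),
                 siteTriadProp = c(A = 0.3, B = 0),
                 nSpecies = 12, ...)
}
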