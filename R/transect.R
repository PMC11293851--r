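## Transect parsing, run-length encoding and network construction.

DEFAULT_COLUMNS <- c(survey_id = "survey_id", site = "site",
                     depth = "depth_m", aspect = "aspect",
                     position = "position_cm", species = "species_code")

#' Read per-centimetre transect observations into TransectRecords
#'
#' The input is a UTF-8 CSV with one row per centimetre observation.  The
#' default column names are \code{survey_id, site, depth_m, aspect,
#' position_cm, species_code}; pass \code{columns} to remap any of them.
#' One record is produced per (survey, depth) combination, with codes
#' ordered by position.  Positions within each combination must be the
#' consecutive integers 1, 2, ...; gaps and duplicates are data errors.
#'
#' @param path CSV file path.
#' @param columns named character vector overriding any of
#'   \code{survey_id, site, depth, aspect, position, species}.
#' @return List of \linkS4class{TransectRecord}s in file order.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(survey_id = "T1", site = "A", depth_m = 2,
#'                      aspect = "photophilous", position_cm = 1:4,
#'                      species_code = c("A", "A", "B", "B")),
#'           f, row.names = FALSE)
#' parseTransectTable(f)
#' @export
parseTransectTable <- function(path, columns = character()) {
  if (!file.exists(path)) stop("transect file not found: ", path)
  map <- DEFAULT_COLUMNS
  if (length(columns)) {
    bad <- setdiff(names(columns), names(map))
    if (length(bad)) stop("unknown column mapping key(s): ",
                          paste(bad, collapse = ", "))
    map[names(columns)] <- columns
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("transect file is empty: ", path)
  missing <- map[!map %in% names(df)]
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  key <- paste(df[[map["survey_id"]]], df[[map["depth"]]], sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), factor(key, levels = unique(key))),
                function(idx) {
    sub <- df[idx, , drop = FALSE]
    pos <- as.integer(sub[[map["position"]]])
    ord <- order(pos)
    sub <- sub[ord, , drop = FALSE]
    pos <- pos[ord]
    sid <- sub[[map["survey_id"]]][1]
    expected <- seq_along(pos)
    if (!identical(pos, expected)) {
      bad <- which(pos != expected)[1]
      if (any(duplicated(pos)))
        stop(sprintf("survey %s (depth %s): duplicate position %d",
                     sid, sub[[map["depth"]]][1], pos[anyDuplicated(pos)]))
      stop(sprintf("survey %s (depth %s): missing position %d",
                   sid, sub[[map["depth"]]][1], expected[bad]))
    }
    transectRecord(sid, sub[[map["site"]]][1], sub[[map["depth"]]][1],
                   sub[[map["aspect"]]][1], sub[[map["species"]]])
  })
  unname(out)
}

#' Read a species attribute table
#'
#' CSV columns \code{code, name, phylum, category} (category optional).
#' Codes must be unique.
#'
#' @param path CSV file path.
#' @return data.frame with columns code, name, phylum, category.
#' @export
readSpeciesAttributes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("code", "name", "phylum")
  if (!all(need %in% names(df)))
    stop("species attribute file needs columns: ",
         paste(need, collapse = ", "))
  if (anyDuplicated(df$code))
    stop("duplicate species code(s) in attribute table: ",
         paste(unique(df$code[duplicated(df$code)]), collapse = ", "))
  df$code <- trimws(df$code)
  df$phylum <- ifelse(is.na(df$phylum) | !nzchar(df$phylum),
                      "unknown", df$phylum)
  if (!"category" %in% names(df)) df$category <- NA_character_
  df[, c("code", "name", "phylum", "category")]
}

#' Run-length encode a transect
#'
#' Collapses the per-centimetre codes into maximal same-species segments;
#' concatenating the segments reproduces the codes exactly.  For example
#' the sequence \code{AAAAABBBBCCAA} encodes to runs A@1(5), B@6(4),
#' C@10(2), A@12(2).
#'
#' @param record a \linkS4class{TransectRecord}.
#' @return data.frame with columns species, start (1-based cm), length.
#' @export
runLengthEncode <- function(record) {
  stopifnot(is(record, "TransectRecord"))
  r <- rle(record@codes)
  ends <- cumsum(r$lengths)
  data.frame(species = r$values,
             start = ends - r$lengths + 1L,
             length = r$lengths,
             stringsAsFactors = FALSE)
}

#' Build a co-occurrence network from run segments
#'
#' Every pair of consecutive runs contributes one adjacency observation to
#' the edge between the two species; repeated pairs accumulate
#' multiplicity.  Vertex \code{size} is the species' total centimetres,
#' \code{count} its number of runs.  Runs whose code is in
#' \code{nonSpecies} (unidentifiable substrate) are dropped and break
#' adjacency: the runs on either side are not connected.  A transect is a
#' line, so the last run is not joined back to the first.
#'
#' @param runs data.frame from \code{\link{runLengthEncode}}.
#' @param attrs optional species attribute table
#'   (\code{\link{readSpeciesAttributes}}); species absent from it get
#'   phylum \code{"unknown"}.
#' @param surveyId,site,depth,aspect network metadata.
#' @param nonSpecies codes treated as substrate gaps rather than vertices.
#'   The default drops \code{"BARE"}, \code{"NA"} and empty codes; pass
#'   \code{character(0)} to keep general categories as vertices.
#' @return A \linkS4class{BenthicNetwork}; a single-species transect yields
#'   a one-vertex, zero-edge network reported as not fittable by
#'   \code{\link{isFittable}}.
#' @examples
#' tr <- transectRecord("T1", "siteA", 7, "photophilous",
#'                      strsplit("AAAAABBBBCCAA", "")[[1]])
#' net <- buildNetwork(runLengthEncode(tr), surveyId = "T1")
#' vertexTable(net)
#' edgeTable(net)
#' @export
buildNetwork <- function(runs, attrs = NULL, surveyId = "unknown",
                         site = "unknown", depth = 1,
                         aspect = "unknown",
                         nonSpecies = c("BARE", "NA", "")) {
  stopifnot(is.data.frame(runs), nrow(runs) >= 1,
            all(c("species", "length") %in% names(runs)))
  keep <- !runs$species %in% nonSpecies
  ## segment id increments across each dropped run so adjacency breaks there
  seg <- cumsum(!keep)
  runs <- cbind(runs, .seg = seg)[keep, , drop = FALSE]
  if (!nrow(runs)) stop("no species runs left after removing non-species codes")

  size <- tapply(runs$length, runs$species, sum)
  count <- tapply(rep(1L, nrow(runs)), runs$species, sum)
  codes <- sort(names(size))
  phylum <- rep("unknown", length(codes))
  if (!is.null(attrs)) {
    m <- match(codes, attrs$code)
    phylum[!is.na(m)] <- attrs$phylum[m[!is.na(m)]]
  }
  vertices <- data.frame(code = codes,
                         size = as.numeric(size[codes]),
                         count = as.integer(count[codes]),
                         phylum = phylum, stringsAsFactors = FALSE)

  n <- nrow(runs)
  edges <- data.frame(u = character(), v = character(),
                      multiplicity = integer(), stringsAsFactors = FALSE)
  if (n >= 2) {
    a <- runs$species[-n]; b <- runs$species[-1]
    ok <- runs$.seg[-n] == runs$.seg[-1]   # no edge across a substrate gap
    a <- a[ok]; b <- b[ok]
    if (length(a)) {
      u <- pmin(a, b); v <- pmax(a, b)
      tab <- table(paste(u, v, sep = "\r"))
      uv <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
      edges <- data.frame(u = uv[, 1], v = uv[, 2],
                          multiplicity = as.integer(tab),
                          stringsAsFactors = FALSE)
      edges <- edges[order(edges$u, edges$v), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  new("BenthicNetwork", vertices = vertices, edges = edges,
      surveyId = as.character(surveyId), site = as.character(site),
      depth = as.numeric(depth), aspect = as.character(aspect))
}

#' Build networks for every record of a parsed transect table
#'
#' @param records list of \linkS4class{TransectRecord}s.
#' @param attrs optional species attribute table.
#' @param nonSpecies see \code{\link{buildNetwork}}.
#' @return list of \linkS4class{BenthicNetwork}s.
#' @export
buildNetworks <- function(records, attrs = NULL,
                          nonSpecies = c("BARE", "NA", "")) {
  lapply(records, function(r)
    buildNetwork(runLengthEncode(r), attrs = attrs,
                 surveyId = r@surveyId, site = r@site, depth = r@depth,
                 aspect = r@aspect, nonSpecies = nonSpecies))
}
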