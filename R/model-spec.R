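## Model specification mini-language and per-network term expansion.

parseOneTerm <- function(txt) {
  txt <- trimws(txt)
  if (txt == "edges") return(list(type = "edges"))
  m <- regmatches(txt, regexec("^(gwesp|nodecov|nodefactor)\\((.*)\\)$", txt))[[1]]
  if (length(m) != 3)
    stop("cannot parse model term: '", txt, "'")
  fun <- m[2]
  args <- trimws(strsplit(m[3], ",")[[1]])
  strip <- function(a) gsub("^['\"]|['\"]$", "", a)
  if (fun == "gwesp") {
    decay <- suppressWarnings(as.numeric(args[1]))
    if (is.na(decay)) stop("gwesp needs a numeric decay: '", txt, "'")
    if (decay < 0) stop("gwesp decay must be >= 0")
    if (length(args) > 1) {
      fx <- gsub("\\s", "", paste(args[-1], collapse = ","))
      if (grepl("fixed=FALSE", fx, fixed = TRUE))
        stop("only fixed-decay gwesp is supported")
    }
    return(list(type = "gwesp", decay = decay))
  }
  attr <- strip(args[1])
  if (!nzchar(attr)) stop(fun, " needs an attribute name: '", txt, "'")
  list(type = fun, attr = attr)
}

#' Specify an ERGM from a formula-like string
#'
#' Supported terms: \code{edges}; \code{gwesp(decay, fixed)} (geometrically
#' weighted edgewise shared partners, fixed decay only);
#' \code{nodecov(attr)} for a quantitative vertex covariate;
#' \code{nodefactor(attr)} for a categorical vertex attribute, where
#' \code{attr} may be \code{vertex.names} (the species codes) or
#' \code{phylum}.  Factor levels are discovered per network and the
#' lexicographically first level is the omitted reference.
#'
#' @param formula e.g.
#'   \code{"edges + gwesp(0.25, fixed) + nodecov(size) + nodecov(count)"}.
#' @return An \linkS4class{ErgmModel}.
#' @examples
#' ergmModel("edges + gwesp(0.25, fixed)")
#' presetModel("model2")
#' @export
ergmModel <- function(formula) {
  parts <- strsplit(formula, "+", fixed = TRUE)[[1]]
  terms <- lapply(parts, parseOneTerm)
  new("ErgmModel", terms = terms, formula = trimws(formula))
}

#' @describeIn ergmModel The three model presets used throughout the
#'   pipeline: \code{model1} (edges + gwesp(0.25, fixed) + nodecov(size) +
#'   nodecov(count)), \code{model1A} (the same without the gwesp term) and
#'   \code{model2} (edges + nodefactor(vertex.names)).
#' @param name preset name.
#' @export
presetModel <- function(name = c("model1", "model1A", "model2")) {
  name <- match.arg(name)
  ergmModel(switch(name,
    model1 = "edges + gwesp(0.25, fixed) + nodecov(size) + nodecov(count)",
    model1A = "edges + nodecov(size) + nodecov(count)",
    model2 = "edges + nodefactor(vertex.names)"))
}

vertexAttribute <- function(vertices, attr) {
  if (attr == "vertex.names") return(vertices$code)
  if (!attr %in% names(vertices))
    stop("vertex attribute not found: ", attr)
  val <- vertices[[attr]]
  if (anyNA(val)) {
    bad <- vertices$code[which(is.na(val))[1]]
    stop("vertex ", bad, " is missing attribute '", attr, "'")
  }
  val
}

## Expand model terms against a vertex table into the flat descriptors the
## C++ kernels consume: list(kind, decay, x) plus a name per expanded term.
## kind: 0 edges, 1 gwesp, 2 linear covariate (nodecov or factor indicator).
expandTerms <- function(model, vertices) {
  stopifnot(is(model, "ErgmModel"), is.data.frame(vertices))
  n <- nrow(vertices)
  out <- list()
  for (t in model@terms) {
    if (t$type == "edges") {
      out[[length(out) + 1L]] <-
        list(kind = 0L, decay = 0, x = numeric(n), name = "edges")
    } else if (t$type == "gwesp") {
      out[[length(out) + 1L]] <-
        list(kind = 1L, decay = t$decay, x = numeric(n),
             name = sprintf("gwesp.fixed.%g", t$decay))
    } else if (t$type == "nodecov") {
      x <- as.numeric(vertexAttribute(vertices, t$attr))
      out[[length(out) + 1L]] <-
        list(kind = 2L, decay = 0, x = x,
             name = paste0("nodecov.", t$attr))
    } else { # nodefactor: reference = lexicographically first level
      val <- as.character(vertexAttribute(vertices, t$attr))
      levels <- sort(unique(val))
      for (l in levels[-1]) {
        out[[length(out) + 1L]] <-
          list(kind = 2L, decay = 0, x = as.numeric(val == l),
               name = paste0("nodefactor.", t$attr, ".", l))
      }
    }
  }
  if (!length(out)) stop("model expands to zero terms")
  out
}

termNames <- function(expanded) vapply(expanded, function(t) t$name, "")

## Does every term have dyad-independent change statistics?
isDyadIndependent <- function(model) {
  !any(vapply(model@terms, function(t) t$type == "gwesp", TRUE))
}

#' Sufficient statistics of a network under a model
#'
#' \code{edges} counts simple edges; \code{nodecov} sums the covariate over
#' both endpoints of every edge; \code{nodefactor} counts edge endpoints at
#' each non-reference level; \code{gwesp} is the geometrically weighted
#' edgewise shared partner statistic (see \code{\link{gwespStatistic}}).
#'
#' @param network a \linkS4class{BenthicNetwork}.
#' @param model an \linkS4class{ErgmModel}.
#' @return Named numeric vector, one value per expanded term.
#' @export
computeStatistics <- function(network, model) {
  stopifnot(is(network, "BenthicNetwork"))
  if (numVertices(network) < 1) stop("network has no vertices")
  ex <- expandTerms(model, network@vertices)
  stats <- cpp_network_stats(asAdjacency(network), ex)
  setNames(as.numeric(stats), termNames(ex))
}

#' Geometrically weighted edgewise shared partner statistic
#'
#' For a simple graph, \eqn{e^{\tau} \sum_{k \ge 1} [1 - (1 -
#' e^{-\tau})^k]\, EP_k}, where \eqn{EP_k} is the number of edges whose
#' endpoints have exactly \eqn{k} common neighbours.  The decay \eqn{\tau}
#' down-weights additional shared partners, which is what keeps the
#' statistic usable where a raw triangle count degenerates.
#'
#' @param network a \linkS4class{BenthicNetwork} (or square 0/1 adjacency
#'   matrix).
#' @param decay non-negative decay \eqn{\tau}.
#' @return The statistic value.
#' @examples
#' tr <- transectRecord("T1", "s", 2, "unknown",
#'                      c("A", "B", "C", "A", "B", "C"))
#' gwespStatistic(buildNetwork(runLengthEncode(tr)), 0.25)
#' @export
gwespStatistic <- function(network, decay = 0.25) {
  if (decay < 0) stop("gwesp decay must be >= 0")
  A <- if (is.matrix(network)) {
    storage.mode(network) <- "integer"; network
  } else asAdjacency(network)
  ex <- list(list(kind = 1L, decay = decay, x = numeric(nrow(A)),
                  name = "gwesp"))
  as.numeric(cpp_network_stats(A, ex))
}

#' Change statistics of one dyad toggle
#'
#' Returns \eqn{\Delta g = g(y + ij) - g(y - ij)}: the difference each
#' statistic would experience if the edge between \code{i} and \code{j}
#' were switched on, computed locally from the dyad's neighbourhood.
#'
#' @param network a \linkS4class{BenthicNetwork}.
#' @param model an \linkS4class{ErgmModel}.
#' @param i,j vertex codes (or 1-based indices); must differ.
#' @return Named numeric vector of changes.
#' @export
changeStatistics <- function(network, model, i, j) {
  codes <- network@vertices$code
  ii <- if (is.character(i)) match(i, codes) else as.integer(i)
  jj <- if (is.character(j)) match(j, codes) else as.integer(j)
  if (is.na(ii) || is.na(jj)) stop("unknown vertex")
  if (ii == jj) stop("i and j must differ")
  ex <- expandTerms(model, network@vertices)
  d <- cpp_change_stats(asAdjacency(network), ii - 1L, jj - 1L, ex)
  setNames(as.numeric(d), termNames(ex))
}
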