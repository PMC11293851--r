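## Network serialization: GraphML (via igraph) or paired CSV files.

csvPaths <- function(path) {
  base <- sub("\\.csv$", "", path)
  list(vertices = paste0(base, "_vertices.csv"),
       edges = paste0(base, "_edges.csv"),
       meta = paste0(base, "_meta.csv"))
}

#' Write a co-occurrence network to disk
#'
#' \code{format = "graphml"} writes a single GraphML file carrying vertex
#' attributes (size, count, phylum), edge multiplicities and the survey
#' metadata as graph attributes.  \code{format = "edge-csv"} writes three
#' CSVs sharing a base path: \code{*_vertices.csv} (code, size, count,
#' phylum), \code{*_edges.csv} (u, v, multiplicity) and \code{*_meta.csv}.
#'
#' @param network a \linkS4class{BenthicNetwork}.
#' @param path output file (GraphML) or base path (edge-csv).
#' @param format \code{"graphml"} or \code{"edge-csv"}.
#' @return \code{path}, invisibly.
#' @export
writeNetwork <- function(network, path, format = c("graphml", "edge-csv")) {
  format <- match.arg(format)
  stopifnot(is(network, "BenthicNetwork"))
  if (format == "graphml") {
    igraph::write_graph(asIgraph(network), path, format = "graphml")
  } else {
    p <- csvPaths(path)
    write.csv(network@vertices, p$vertices, row.names = FALSE)
    write.csv(network@edges, p$edges, row.names = FALSE)
    write.csv(data.frame(surveyId = network@surveyId, site = network@site,
                         depth = network@depth, aspect = network@aspect),
              p$meta, row.names = FALSE)
  }
  invisible(path)
}

#' Read a co-occurrence network written by \code{\link{writeNetwork}}
#'
#' @param path file (GraphML) or base path (edge-csv).
#' @param format \code{"graphml"} or \code{"edge-csv"}.
#' @return A \linkS4class{BenthicNetwork}.
#' @export
readNetwork <- function(path, format = c("graphml", "edge-csv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    if (!file.exists(path)) stop("network file not found: ", path)
    g <- igraph::read_graph(path, format = "graphml")
    vertices <- data.frame(
      code = igraph::vertex_attr(g, "name"),
      size = as.numeric(igraph::vertex_attr(g, "size")),
      count = as.integer(igraph::vertex_attr(g, "count")),
      phylum = as.character(igraph::vertex_attr(g, "phylum")),
      stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(u = pmin(el[, 1], el[, 2]),
                        v = pmax(el[, 1], el[, 2]),
                        multiplicity =
                          as.integer(igraph::edge_attr(g, "multiplicity")),
                        stringsAsFactors = FALSE)
    meta <- list(surveyId = igraph::graph_attr(g, "surveyId"),
                 site = igraph::graph_attr(g, "site"),
                 depth = igraph::graph_attr(g, "depth"),
                 aspect = igraph::graph_attr(g, "aspect"))
  } else {
    p <- csvPaths(path)
    for (f in unlist(p)) if (!file.exists(f)) stop("network file not found: ", f)
    vertices <- read.csv(p$vertices, stringsAsFactors = FALSE)
    edges <- read.csv(p$edges, stringsAsFactors = FALSE)
    if (!nrow(edges))
      edges <- data.frame(u = character(), v = character(),
                          multiplicity = integer())
    m <- read.csv(p$meta, stringsAsFactors = FALSE)
    meta <- as.list(m[1, ])
  }
  vertices <- vertices[order(vertices$code), , drop = FALSE]
  rownames(vertices) <- NULL
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) && any(edges$multiplicity < 1))
    stop("malformed network file: edge multiplicity below 1")
  new("BenthicNetwork", vertices = vertices, edges = edges,
      surveyId = as.character(meta$surveyId), site = as.character(meta$site),
      depth = as.numeric(meta$depth), aspect = as.character(meta$aspect))
}
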