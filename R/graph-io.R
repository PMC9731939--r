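# Reading and writing undirected simple graphs in the three standard
# interchange formats, plus ground-truth label CSVs. Node identifiers are
# remapped to contiguous integers 1..n; all package matrices index nodes
# in that order.

graph_formats <- c("edgelist", "gml", "graphml")

#' Read an undirected simple graph from a file
#'
#' Supported formats: whitespace-delimited edge list, GML, GraphML.
#' Directed graphs, self-loops and duplicate edges are rejected. Node
#' identifiers are remapped to contiguous integers; the original
#' identifiers are kept in the `name` vertex attribute when present.
#'
#' @param path File path.
#' @param format One of `"edgelist"`, `"gml"`, `"graphml"`; guessed from
#'   the file extension when missing.
#' @param require_connected Reject disconnected graphs (default TRUE; the
#'   experiment pipeline needs connected graphs, feature-only use may not).
#' @return An igraph object.
#' @export
read_graph_file <- function(path, format = NULL, require_connected = TRUE) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               gml = "gml", graphml = "graphml", "edgelist")
  format <- match.arg(format, graph_formats)
  g <- switch(format,
    edgelist = {
      el <- as.matrix(read.table(path))
      ids <- sort(unique(as.vector(el)))
      g0 <- igraph::make_empty_graph(length(ids), directed = FALSE)
      g0 <- igraph::add_edges(g0, t(matrix(match(el, ids), ncol = 2)))
      igraph::set_vertex_attr(g0, "name", value = as.character(ids))
    },
    gml = igraph::read_graph(path, format = "gml"),
    graphml = igraph::read_graph(path, format = "graphml")
  )
  if (igraph::is_directed(g)) abort("directed graphs are not supported")
  if (any(igraph::which_loop(g))) abort("graph has self-loops")
  if (any(igraph::which_multiple(g))) abort("graph has duplicate edges")
  if (require_connected && !igraph::is_connected(g)) {
    abort("graph is disconnected; pass require_connected = FALSE for feature-only use")
  }
  g
}

#' @rdname read_graph_file
#' @param graph An igraph object or `cd_graph`.
#' @export
write_graph_file <- function(graph, path, format = NULL) {
  g <- as_cd_igraph(graph)
  format <- format %||% switch(tolower(tools::file_ext(path)),
                               gml = "gml", graphml = "graphml", "edgelist")
  format <- match.arg(format, graph_formats)
  if (format == "edgelist") {
    ends <- igraph::as_edgelist(g, names = FALSE)
    utils::write.table(ends - 1L, path, row.names = FALSE, col.names = FALSE)
  } else {
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

#' Read / write planted ground-truth labels
#'
#' Two-column CSV (`node`, `label`).
#'
#' @param x Tibble with columns `node`, `label` (or a `cd_graph`).
#' @param path File path.
#' @export
write_ground_truth <- function(x, path) {
  gt <- if (inherits(x, "cd_graph")) x$ground_truth else x
  write.csv(gt[, c("node", "label")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  as_tibble(read.csv(path))[, c("node", "label")]
}
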