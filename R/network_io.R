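#' Export a network to GraphML or an edge-list TSV
#'
#' Networks in this package are undirected `igraph` objects whose edges
#' carry a `weight` (signed association score) and a `sign` attribute
#' (`"+"` or `"-"`), and whose vertices may carry `kind`
#' (`"taxon"`/`"function"`) and `module` attributes. GraphML preserves
#' all attributes; the edge-list TSV writes one row per edge with columns
#' `source`, `target`, `weight`, `sign`, plus `support` and `combined_p`
#' when present on the edges.
#'
#' @param net An undirected `igraph` graph.
#' @param path Output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "igraph"))
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net, names = TRUE)
    df <- data.frame(source = el[, 1], target = el[, 2],
                     stringsAsFactors = FALSE)
    for (attr in c("weight", "sign", "support", "combined_p")) {
      if (attr %in% igraph::edge_attr_names(net)) {
        df[[attr]] <- igraph::edge_attr(net, attr)
      }
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Import a network written by [export_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return An undirected `igraph` graph.
#' @export
import_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(df, directed = FALSE)
    g
  }
}

#' Attach signs to edge weights
#'
#' Ensures every edge has a `sign` attribute consistent with the sign of
#' its weight.
#'
#' @param net An `igraph` graph with a `weight` edge attribute.
#' @return The graph with a `sign` edge attribute.
#' @export
sign_edges <- function(net) {
  w <- igraph::E(net)$weight
  igraph::E(net)$sign <- ifelse(w < 0, "-", "+")
  net
}
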