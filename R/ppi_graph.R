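#' Construct an interaction graph
#'
#' Builds a simple undirected weighted graph from an edge table. This is the
#' central data structure of the package: nodes are gene/protein identifiers
#' (non-empty strings) and edges carry an interaction confidence weight in
#' (0, 1], as in STRING "combined score" exports rescaled to unit range.
#'
#' Identifiers are whitespace-trimmed and case-sensitive. Self-loops are
#' dropped (with a warning giving the count), duplicate edges -- including
#' reversed duplicates, since the graph is undirected -- are collapsed keeping
#' the maximum weight, and edges with non-positive weight are rejected.
#'
#' @param edges data frame with columns `from`, `to` and optionally `weight`
#'   (default 1); may have zero rows.
#' @param nodes character vector of additional (possibly isolated) node
#'   identifiers to include besides the edge endpoints.
#' @param name free-text label stored as the graph `$name` attribute.
#' @return an [igraph::igraph] object (undirected, simple, with a `weight`
#'   edge attribute).
#' @examples
#' g <- ppi_graph(data.frame(from = "A", to = "B", weight = 0.9), nodes = "C")
#' igraph::vcount(g) # 3
#' @export
ppi_graph <- function(edges = data.frame(from = character(), to = character()),
                      nodes = character(), name = "") {
  stopifnot(is.data.frame(edges))
  if (!all(c("from", "to") %in% names(edges))) {
    stop("`edges` must have columns 'from' and 'to'")
  }
  from <- trimws(as.character(edges$from))
  to <- trimws(as.character(edges$to))
  w <- if ("weight" %in% names(edges)) as.numeric(edges$weight) else
    rep(1, length(from))
  if (any(!nzchar(from)) || any(!nzchar(to))) {
    stop("node identifiers must be non-empty strings")
  }
  keep <- from != to
  n_loops <- sum(!keep)
  if (n_loops > 0) {
    warning(sprintf("dropped %d self-loop edge(s)", n_loops))
    from <- from[keep]; to <- to[keep]; w <- w[keep]
  }
  if (any(is.na(w)) || any(w <= 0) || any(w > 1)) {
    stop("edge weights must lie in (0, 1]")
  }
  # canonical unordered key, collapse duplicates keeping the max weight
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    w <- tapply(w, key, max)
    pieces <- strsplit(names(w), "\r", fixed = TRUE)
    lo <- vapply(pieces, `[`, character(1), 1L)
    hi <- vapply(pieces, `[`, character(1), 2L)
    w <- as.numeric(w)
  }
  all_nodes <- sort(unique(c(lo, hi, trimws(as.character(nodes)))),
                    method = "radix")
  g <- igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, weight = w, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = all_nodes, stringsAsFactors = FALSE)
  )
  g$name <- name
  g
}

#' @keywords internal
#' @noRd
edge_weights <- function(graph) {
  if ("weight" %in% igraph::edge_attr_names(graph)) {
    igraph::E(graph)$weight
  } else {
    rep(1, igraph::ecount(graph))
  }
}

#' Node identifiers of a graph in byte order
#' @keywords internal
#' @noRd
sorted_nodes <- function(graph) {
  sort(igraph::V(graph)$name, method = "radix")
}

#' @keywords internal
#' @noRd
check_members <- function(graph, members) {
  members <- as.character(members)
  missing <- setdiff(members, igraph::V(graph)$name)
  if (length(missing) > 0) {
    stop("node(s) not in graph: ", paste(missing, collapse = ", "))
  }
  members
}

#' Induced subgraph on a node set
#'
#' Returns the subgraph containing the given nodes and all (and only) the
#' edges of `graph` with both endpoints in the set. Used to extract the
#' crucial-node subinteractome.
#'
#' @param graph an interaction graph.
#' @param nodes character vector of node identifiers, all present in `graph`.
#' @return an igraph object.
#' @export
extract_subnetwork <- function(graph, nodes) {
  nodes <- check_members(graph, unique(as.character(nodes)))
  igraph::induced_subgraph(graph, nodes)
}
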