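#' Read a STRING-style edge list
#'
#' Parses a whitespace- or tab-separated edge list with columns
#' `node1 node2 [combined_score]`, the format of STRING network exports.
#' The score column is auto-detected as being on the \[0, 1000\] or \[0, 1\]
#' scale (any value > 1 means the whole column is divided by 1000) and a
#' header row is recognised by a non-numeric third field. Edges whose score
#' falls below `score_threshold` are excluded, but their endpoints are kept
#' as (possibly isolated) nodes -- this mirrors how a STRING disease query
#' returns genes that end up isolated in the interactome. Rows without a
#' score column get weight 1. Self-loop rows are dropped with a warning and
#' duplicate (or reversed-duplicate) rows are collapsed keeping the maximum
#' score.
#'
#' @param path path to the edge-list file.
#' @param score_threshold minimum confidence score, on the unit scale, for an
#'   edge to be kept. Default 0.4 (STRING's conventional medium confidence).
#' @return an interaction graph (see [ppi_graph()]).
#' @export
read_string_tsv <- function(path, score_threshold = 0.4) {
  stopifnot(is.numeric(score_threshold), length(score_threshold) == 1,
            score_threshold >= 0, score_threshold <= 1)
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop("cannot read input file '", path,
                                             "': ", conditionMessage(e)))
  lines <- trimws(lines)
  lineno <- seq_along(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]; lineno <- lineno[keep]
  if (length(lines) == 0) return(ppi_graph())
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf < 2)) {
    stop("parse error at line ", lineno[which(nf < 2)[1]],
         ": fewer than 2 columns")
  }
  third <- vapply(fields, function(f) if (length(f) >= 3) f[3] else NA_character_,
                  character(1))
  # header row: first line whose 3rd field exists and is not numeric
  if (!is.na(third[1]) && is.na(suppressWarnings(as.numeric(third[1])))) {
    fields <- fields[-1]; third <- third[-1]; lineno <- lineno[-1]
    if (length(fields) == 0) return(ppi_graph())
  }
  score <- suppressWarnings(as.numeric(third))
  bad <- !is.na(third) & is.na(score)
  if (any(bad)) {
    stop("parse error at line ", lineno[which(bad)[1]],
         ": non-numeric score field")
  }
  if (any(score > 1, na.rm = TRUE)) score <- score / 1000
  score[is.na(score)] <- 1.0
  from <- vapply(fields, `[`, character(1), 1L)
  to <- vapply(fields, `[`, character(1), 2L)
  pass <- score >= score_threshold & score > 0
  n_loop <- sum(from == to & pass)
  if (n_loop > 0) warning(sprintf("dropped %d self-loop row(s)", n_loop))
  edges <- data.frame(from = from[pass & from != to],
                      to = to[pass & from != to],
                      weight = score[pass & from != to],
                      stringsAsFactors = FALSE)
  ppi_graph(edges, nodes = unique(c(trimws(from), trimws(to))))
}

#' Read a SIF (simple interaction format) file
#'
#' Each line is either a single node identifier (an isolated node) or
#' `nodeA relation nodeB [nodeC ...]`, producing one unit-weight edge per
#' (nodeA, nodeX) pair. Self-loops are dropped.
#'
#' @param path path to the SIF file.
#' @return an interaction graph.
#' @export
read_sif <- function(path) {
  lines <- tryCatch(readLines(path, warn = FALSE),
                    error = function(e) stop("cannot read input file '", path,
                                             "': ", conditionMessage(e)))
  lines <- trimws(lines)
  lineno <- which(nzchar(lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(ppi_graph())
  fields <- strsplit(lines, "[\t ]+")
  nf <- lengths(fields)
  if (any(nf == 2)) {
    stop("parse error at line ", lineno[which(nf == 2)[1]],
         ": relation given but no target node")
  }
  singles <- unlist(lapply(fields[nf == 1], `[`, 1L))
  eds <- fields[nf >= 3]
  from <- rep(vapply(eds, `[`, character(1), 1L),
              vapply(eds, function(f) length(f) - 2L, integer(1)))
  to <- as.character(unlist(lapply(eds, function(f) f[-(1:2)])))
  from <- as.character(from)
  keep <- from != to
  edges <- data.frame(from = from[keep], to = to[keep],
                      stringsAsFactors = FALSE)
  nodes <- unique(c(singles, from, to))
  ppi_graph(edges, nodes = nodes)
}

#' Write a graph as SIF
#'
#' Deterministic output: one `u <relation> v` line per edge with the
#' byte-order-smaller endpoint first, sorted; isolated nodes are written as
#' single-token lines at the end.
#'
#' @param graph an interaction graph.
#' @param path output path.
#' @param relation relation label written in the second column.
#' @export
write_sif <- function(graph, path, relation = "pp") {
  ends <- igraph::as_edgelist(graph)
  lines <- character(0)
  if (nrow(ends) > 0) {
    lo <- pmin(ends[, 1], ends[, 2])
    hi <- pmax(ends[, 1], ends[, 2])
    lines <- sort(paste(lo, relation, hi, sep = "\t"), method = "radix")
  }
  iso <- igraph::V(graph)$name[igraph::degree(graph) == 0]
  lines <- c(lines, sort(iso, method = "radix"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot write '", path, "': ", conditionMessage(e)))
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Whole-graph summary statistics
#'
#' Computes the node/edge counts, density, average clustering coefficient
#' and the connected-component decomposition, the quantities used to
#' characterise an interactome at a glance (density of a sparse disease
#' network is typically a few percent; the component decomposition separates
#' the main interacting component from isolated and paired genes).
#'
#' Density is `2 m / (n (n - 1))` for `n >= 2` (0 otherwise). The clustering
#' coefficient is by default the network average of the local (Watts-Strogatz)
#' clustering coefficient with nodes of degree < 2 contributing 0, the
#' NetworkAnalyzer convention; `clustering = "transitivity"` gives the global
#' triangle-to-triple ratio instead.
#'
#' @param graph an interaction graph.
#' @param clustering `"local_average"` (default) or `"transitivity"`.
#' @return an object of class `ppi_graph_summary`: a list with `n_nodes`,
#'   `n_edges`, `density`, `avg_clustering`, `component_sizes` (descending),
#'   `n_isolated` and `n_paired` (nodes living in size-2 components).
#' @export
summarize_graph <- function(graph, clustering = c("local_average",
                                                  "transitivity")) {
  clustering <- match.arg(clustering)
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  density <- if (n >= 2) 2 * m / (n * (n - 1)) else 0
  avg_clust <- if (n == 0) 0 else if (clustering == "local_average") {
    mean(igraph::transitivity(graph, type = "localundirected",
                              isolates = "zero"))
  } else {
    t <- igraph::transitivity(graph, type = "global")
    if (is.nan(t)) 0 else t
  }
  comp_sizes <- if (n == 0) integer(0) else
    sort(igraph::components(graph)$csize, decreasing = TRUE)
  out <- list(
    n_nodes = n,
    n_edges = m,
    density = density,
    avg_clustering = avg_clust,
    component_sizes = as.integer(comp_sizes),
    n_isolated = sum(comp_sizes == 1L),
    n_paired = 2L * sum(comp_sizes == 2L)
  )
  class(out) <- "ppi_graph_summary"
  out
}

#' @export
print.ppi_graph_summary <- function(x, ...) {
  cat(sprintf(
    "Interaction graph: %d nodes, %d edges\n  density %.4g, avg clustering %.4g\n",
    x$n_nodes, x$n_edges, x$density, x$avg_clustering))
  cat(sprintf("  components: main %s, %d isolated node(s), %d paired node(s)\n",
              if (length(x$component_sizes)) x$component_sizes[1] else 0,
              x$n_isolated, x$n_paired))
  invisible(x)
}

#' Write a result table as TSV
#'
#' UTF-8, tab-separated, header row, numeric columns rendered with 6
#' significant digits. Writing the same table twice yields byte-identical
#' files; row order is whatever the caller established (each pipeline table
#' has a stated sort key).
#'
#' @param records a data frame.
#' @param path output path.
#' @export
write_tables <- function(records, path) {
  stopifnot(!is.null(records))
  records <- as.data.frame(records)
  for (j in seq_along(records)) {
    col <- records[[j]]
    if (is.double(col)) {
      records[[j]] <- formatC(col, format = "g", digits = 6)
    }
  }
  con <- tryCatch(file(path, "w", encoding = "UTF-8"), error = function(e)
    stop("cannot write '", path, "': ", conditionMessage(e)))
  on.exit(close(con))
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "")
  invisible(path)
}

#' Write a graph summary as JSON
#' @param summary a `ppi_graph_summary`.
#' @param path output path.
#' @export
write_graph_summary <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
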