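# Crucial-node selection: hubs by a degree threshold, bottlenecks and
# high-closeness nodes by top-fraction ranking, and their intersection.

#' Selection criteria for crucial nodes
#'
#' @param hub_sd_multiplier non-negative multiplier `k` in the hub rule
#'   `degree > mean + k * SD` (default 2).
#' @param top_fraction fraction in (0, 1\] of nodes kept as bottlenecks /
#'   high-closeness nodes (default 0.05, i.e. the top 5 percent).
#' @param sd_mode `"sample"` (n - 1 denominator, default) or `"population"`.
#' @return a `selection_criteria` list.
#' @export
selection_criteria <- function(hub_sd_multiplier = 2, top_fraction = 0.05,
                               sd_mode = c("sample", "population")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(is.numeric(hub_sd_multiplier), hub_sd_multiplier >= 0,
            is.numeric(top_fraction), top_fraction > 0, top_fraction <= 1)
  structure(list(hub_sd_multiplier = hub_sd_multiplier,
                 top_fraction = top_fraction, sd_mode = sd_mode),
            class = "selection_criteria")
}

#' Hub degree threshold: mean + k * SD
#'
#' @param degrees vector of node degrees (all nodes of the graph, including
#'   isolated ones).
#' @param criteria a [selection_criteria()].
#' @return the threshold `mean(degrees) + k * sd(degrees)`.
#' @export
hub_threshold <- function(degrees, criteria = selection_criteria()) {
  if (length(degrees) == 0) stop("`degrees` must be non-empty")
  s <- if (criteria$sd_mode == "sample") {
    if (length(degrees) < 2) {
      stop("sample SD is undefined for a single degree; use sd_mode = \"population\"")
    }
    stats::sd(degrees)
  } else {
    sqrt(mean((degrees - mean(degrees))^2))
  }
  mean(degrees) + criteria$hub_sd_multiplier * s
}

#' Top fraction of nodes by a centrality metric
#'
#' Returns exactly `ceiling(fraction * n)` node identifiers, ranked by the
#' metric descending with node id ascending (byte order) as the tie-break, so
#' the selection is deterministic.
#'
#' @param table a [centrality_table()] data frame.
#' @param metric `"betweenness"` or `"closeness"`.
#' @param fraction fraction in (0, 1\].
#' @return character vector of selected node ids (sorted by byte order).
#' @export
top_fraction <- function(table, metric = c("betweenness", "closeness"),
                         fraction = 0.05) {
  metric <- match.arg(metric)
  stopifnot(nrow(table) > 0, fraction > 0, fraction <= 1)
  k <- ceiling(fraction * nrow(table))
  ord <- order(-table[[metric]], table$node, method = "radix")
  sort(table$node[ord][seq_len(k)], method = "radix")
}

#' Select crucial nodes
#'
#' Applies the three topological filters and intersects them: hubs are nodes
#' with degree strictly greater than `mean + k * SD` over all node degrees,
#' bottlenecks are the top fraction by betweenness, high-closeness nodes the
#' top fraction by closeness, and the crucial set (the candidate biomarker
#' panel) is the three-way intersection.
#'
#' @param table a [centrality_table()] data frame (one row per graph node).
#' @param criteria a [selection_criteria()].
#' @return an object of class `ppi_selection`: list with sorted node sets
#'   `hubs`, `bottlenecks`, `high_closeness`, `crucial`, the numeric
#'   `degree_threshold` and the `criteria` used.
#' @export
select_crucial <- function(table, criteria = selection_criteria()) {
  stopifnot(nrow(table) > 0)
  thr <- hub_threshold(table$degree, criteria)
  hubs <- sort(table$node[table$degree > thr], method = "radix")
  bottlenecks <- top_fraction(table, "betweenness", criteria$top_fraction)
  high_closeness <- top_fraction(table, "closeness", criteria$top_fraction)
  crucial <- sort(intersect(intersect(hubs, bottlenecks), high_closeness),
                  method = "radix")
  structure(list(hubs = hubs, bottlenecks = bottlenecks,
                 high_closeness = high_closeness, crucial = crucial,
                 degree_threshold = thr, criteria = criteria),
            class = "ppi_selection")
}

#' @export
print.ppi_selection <- function(x, ...) {
  cat(sprintf(paste0(
    "Crucial-node selection\n",
    "  degree threshold (mean + %g SD): %.4g\n",
    "  hubs: %d, bottlenecks: %d, high-closeness: %d\n",
    "  crucial (triple intersection): %d\n"),
    x$criteria$hub_sd_multiplier, x$degree_threshold,
    length(x$hubs), length(x$bottlenecks), length(x$high_closeness),
    length(x$crucial)))
  if (length(x$crucial)) cat("  ", paste(x$crucial, collapse = ", "), "\n")
  invisible(x)
}

#' Selection result as a per-node table
#'
#' One row per node with logical columns `hub`, `bottleneck`,
#' `high_closeness`, `crucial`, in the row order of `table`.
#'
#' @param selection a `ppi_selection`.
#' @param table the centrality table the selection was computed from.
#' @return data frame.
#' @export
selection_table <- function(selection, table) {
  data.frame(node = table$node,
             degree = table$degree,
             betweenness = table$betweenness,
             closeness = table$closeness,
             hub = table$node %in% selection$hubs,
             bottleneck = table$node %in% selection$bottlenecks,
             high_closeness = table$node %in% selection$high_closeness,
             crucial = table$node %in% selection$crucial,
             stringsAsFactors = FALSE)
}
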