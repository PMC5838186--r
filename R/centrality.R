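# Centrality measures over the interaction graph. Shortest paths are
# unweighted hop counts throughout: the interactome is treated as a plain
# undirected graph even though edges carry confidence scores, matching how
# topology tools report D/BC/CC.

#' @keywords internal
#' @noRd
adjacency_indices <- function(graph) {
  lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
}

#' Degree of every node
#'
#' @param graph an interaction graph.
#' @return named integer vector (names in byte order): number of incident
#'   edges per node.
#' @export
degree_all <- function(graph) {
  d <- igraph::degree(graph)
  nm <- sort(names(d), method = "radix")
  out <- as.integer(d[nm])
  names(out) <- nm
  out
}

#' Betweenness centrality of every node (Brandes' algorithm)
#'
#' Raw betweenness of `v` is the sum over unordered node pairs `(s, t)` with
#' `s != v != t` of the fraction of shortest `s`-`t` paths passing through
#' `v`. Computed by Brandes' single-source accumulation over unweighted
#' shortest paths. Normalization divides by `(n - 1)(n - 2) / 2` with `n` the
#' total node count of the graph (not the component size), so values lie in
#' \[0, 1\].
#'
#' @param graph an interaction graph.
#' @param normalized divide by the number of node pairs excluding `v`
#'   (default `TRUE`).
#' @return named numeric vector, names in byte order.
#' @export
betweenness_all <- function(graph, normalized = TRUE) {
  n <- igraph::vcount(graph)
  vnames <- igraph::V(graph)$name
  bc <- numeric(n)
  if (n > 2) {
    adj <- adjacency_indices(graph)
    for (s in seq_len(n)) {
      dist <- rep(-1L, n)
      sigma <- numeric(n)
      preds <- vector("list", n)
      order_v <- integer(n) # BFS visit order doubles as the stack
      dist[s] <- 0L
      sigma[s] <- 1
      head <- 1L; tail <- 1L
      order_v[1L] <- s
      while (head <= tail) {
        v <- order_v[head]; head <- head + 1L
        dv1 <- dist[v] + 1L
        for (w in adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dv1
            tail <- tail + 1L
            order_v[tail] <- w
          }
          if (dist[w] == dv1) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      delta <- numeric(n)
      for (i in seq.int(tail, 1L)) {
        w <- order_v[i]
        coef <- (1 + delta[w]) / sigma[w]
        for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] * coef
        if (w != s) bc[w] <- bc[w] + delta[w]
      }
    }
    bc <- bc / 2 # each unordered (s, t) pair accumulated from both ends
    if (normalized) bc <- bc / ((n - 1) * (n - 2) / 2)
  }
  nm <- sort(vnames, method = "radix")
  out <- bc[match(nm, vnames)]
  names(out) <- nm
  out
}

#' Closeness centrality of every node (component-wise)
#'
#' `CC(v) = (|C_v| - 1) / sum_u d(v, u)` where `C_v` is the connected
#' component of `v` and the sum runs over the other nodes of that component.
#' Isolated nodes get 0. Restricting to the component is what makes closeness
#' meaningful on disease interactomes, where a large fraction of the
#' retrieved genes are isolated: values stay in \[0, 1\] with 1 meaning `v`
#' is adjacent to every other node of its component.
#'
#' @param graph an interaction graph.
#' @return named numeric vector, names in byte order.
#' @export
closeness_all <- function(graph) {
  n <- igraph::vcount(graph)
  vnames <- igraph::V(graph)$name
  cc <- numeric(n)
  if (n > 0) {
    adj <- adjacency_indices(graph)
    dist <- integer(n)
    queue <- integer(n)
    for (s in seq_len(n)) {
      dist[] <- -1L
      dist[s] <- 0L
      head <- 1L; tail <- 1L
      queue[1L] <- s
      total <- 0L
      reached <- 0L
      while (head <= tail) {
        v <- queue[head]; head <- head + 1L
        for (w in adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            total <- total + dist[w]
            reached <- reached + 1L
            tail <- tail + 1L
            queue[tail] <- w
          }
        }
      }
      cc[s] <- if (total > 0L) reached / total else 0
    }
  }
  nm <- sort(vnames, method = "radix")
  out <- cc[match(nm, vnames)]
  names(out) <- nm
  out
}

#' Per-node centrality table
#'
#' Assembles degree (D), normalized betweenness (BC) and component-wise
#' closeness (CC) into one record per node, sorted by degree descending with
#' node-id ascending as tie-break -- the layout of a crucial-node table.
#'
#' @param graph an interaction graph.
#' @return data frame with columns `node`, `degree`, `betweenness`,
#'   `closeness`.
#' @export
centrality_table <- function(graph) {
  d <- degree_all(graph)
  if (length(d) == 0) {
    return(data.frame(node = character(), degree = integer(),
                      betweenness = numeric(), closeness = numeric(),
                      stringsAsFactors = FALSE))
  }
  b <- betweenness_all(graph)
  cc <- closeness_all(graph)
  tab <- data.frame(node = names(d), degree = as.integer(d),
                    betweenness = as.numeric(b), closeness = as.numeric(cc),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$degree, tab$node, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
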