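# Brute-force reference implementations, independent of the package's
# algorithms, used as oracles in the tests.

# small named graphs ---------------------------------------------------------

edges_df <- function(from, to, weight = NULL) {
  if (is.null(weight)) data.frame(from = from, to = to,
                                  stringsAsFactors = FALSE)
  else data.frame(from = from, to = to, weight = weight,
                  stringsAsFactors = FALSE)
}

clique_df <- function(members) {
  pairs <- utils::combn(members, 2)
  edges_df(pairs[1, ], pairs[2, ])
}

path_graph <- function(nodes) {
  ppi_graph(edges_df(nodes[-length(nodes)], nodes[-1]))
}

star_graph <- function(center, leaves) {
  ppi_graph(edges_df(rep(center, length(leaves)), leaves))
}

cycle_graph <- function(nodes) {
  ppi_graph(edges_df(nodes, c(nodes[-1], nodes[1])))
}

complete_graph <- function(nodes) {
  ppi_graph(clique_df(nodes))
}

# Erdos-Renyi-style random graph over n named nodes; uses the current RNG
rand_ppi_graph <- function(n, p) {
  nodes <- sprintf("N%02d", seq_len(n))
  if (n < 2) return(ppi_graph(nodes = nodes))
  pairs <- utils::combn(n, 2)
  pick <- stats::runif(ncol(pairs)) < p
  ppi_graph(edges_df(nodes[pairs[1, pick]], nodes[pairs[2, pick]]),
            nodes = nodes)
}

# shortest-path enumeration oracle -------------------------------------------

# All simple paths from s to t over an adjacency list of integer indices.
bf_simple_paths <- function(adj, s, t) {
  paths <- list()
  visited <- rep(FALSE, length(adj))
  rec <- function(v, path) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in adj[[v]]) {
      if (!visited[w]) {
        visited[w] <<- TRUE
        rec(w, c(path, w))
        visited[w] <<- FALSE
      }
    }
  }
  visited[s] <- TRUE
  rec(s, s)
  paths
}

# Betweenness (normalized) and component-wise closeness by enumerating every
# simple path and keeping the shortest ones -- O(n!) but fine for n <= 7.
oracle_centrality <- function(graph) {
  vn <- igraph::V(graph)$name
  n <- length(vn)
  adj <- lapply(igraph::as_adj_list(graph, mode = "all"), as.integer)
  bc <- numeric(n)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  if (n >= 2) {
    for (s in seq_len(n - 1)) {
      for (t in seq.int(s + 1, n)) {
        paths <- bf_simple_paths(adj, s, t)
        if (length(paths) == 0) next
        lens <- lengths(paths) - 1L
        L <- min(lens)
        dist[s, t] <- dist[t, s] <- L
        shortest <- paths[lens == L]
        sigma <- length(shortest)
        for (p in shortest) {
          interior <- p[-c(1L, length(p))]
          bc[interior] <- bc[interior] + 1 / sigma
        }
      }
    }
  }
  if (n > 2) bc <- bc / ((n - 1) * (n - 2) / 2) else bc <- numeric(n)
  cc <- vapply(seq_len(n), function(v) {
    d <- dist[v, -v]
    d <- d[is.finite(d)]
    if (length(d) == 0 || sum(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))
  ord <- order(vn, method = "radix")
  list(betweenness = stats::setNames(bc[ord], vn[ord]),
       closeness = stats::setNames(cc[ord], vn[ord]))
}

# adjacency-matrix summary oracle --------------------------------------------

oracle_summary <- function(graph) {
  n <- igraph::vcount(graph)
  A <- matrix(0, n, n)
  if (igraph::ecount(graph) > 0) {
    el <- igraph::as_edgelist(graph, names = FALSE)
    A[el] <- 1
    A[el[, 2:1, drop = FALSE]] <- 1
  }
  deg <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  local <- ifelse(deg >= 2, tri / (deg * (deg - 1) / 2), 0)
  list(density = if (n >= 2) sum(A) / (n * (n - 1)) else 0,
       avg_clustering = if (n > 0) mean(local) else 0)
}

# Mann-Whitney enumeration oracle --------------------------------------------

# one-sided (x greater) exact p by direct U-statistic enumeration
oracle_mwu_greater <- function(x, y) {
  u_stat <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  pooled <- c(x, y)
  u_obs <- u_stat(x, y)
  combos <- utils::combn(length(pooled), length(x))
  hits <- apply(combos, 2, function(ix) {
    u_stat(pooled[ix], pooled[-ix]) >= u_obs - 1e-9
  })
  mean(hits)
}

# hypergeometric right-tail oracle -------------------------------------------

oracle_hypergeom <- function(k, n, K, N) {
  i <- seq.int(k, min(n, K))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# misc ------------------------------------------------------------------------

jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}

# benchmark-style background of isolated nodes and pairs (no component of
# size >= 3, so no background cluster can reach significance)
scatter_background <- function(n_isolated, n_pairs, prefix = "BG") {
  iso <- sprintf("%sI%03d", prefix, seq_len(n_isolated))
  a <- sprintf("%sP%03da", prefix, seq_len(n_pairs))
  b <- sprintf("%sP%03db", prefix, seq_len(n_pairs))
  list(edges = edges_df(a, b), nodes = iso)
}
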