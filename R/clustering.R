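# Overlapping dense-cluster detection by cohesiveness-greedy growth with a
# one-sided Mann-Whitney significance filter. Cohesiveness of a node set V is
#   f(V) = w_in / (w_in + w_bound + penalty)
# where w_in is the total weight of edges inside V, w_bound the total weight
# of edges crossing the boundary, and the penalty models unobserved
# interactions. Growth applies, from a seed node, the single best
# strictly-improving move (add a boundary node or remove a member) until a
# local maximum is reached.

#' Clustering parameters
#'
#' @param penalty non-negative cohesiveness penalty term (default 2).
#' @param min_size minimum cluster size kept (default 3).
#' @param min_density minimum internal edge density kept (default 0.3).
#' @param overlap_omega match-coefficient threshold at or above which two
#'   clusters are merged, `omega(A, B) = |A n B|^2 / (|A| |B|)` (default 0.8).
#' @param p_threshold significance cutoff: clusters with a one-sided
#'   Mann-Whitney p-value above this are discarded (default 0.001). Note the
#'   exact test has a floor of `1 / choose(2 m, m)` for an `m`-member
#'   cluster, so at 0.001 a significant cluster needs at least 7 members.
#' @param seed_order seeding policy; only `"degree_desc"` is implemented.
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(penalty = 2, min_size = 3L, min_density = 0.3,
                           overlap_omega = 0.8, p_threshold = 0.001,
                           seed_order = "degree_desc") {
  stopifnot(is.numeric(penalty), penalty >= 0,
            min_size >= 2, min_density >= 0, min_density <= 1,
            overlap_omega > 0, overlap_omega <= 1,
            p_threshold > 0, p_threshold < 1,
            identical(seed_order, "degree_desc"))
  structure(list(penalty = penalty, min_size = as.integer(min_size),
                 min_density = min_density, overlap_omega = overlap_omega,
                 p_threshold = p_threshold, seed_order = seed_order),
            class = "cluster_params")
}

#' Cohesiveness of a node set
#'
#' `w_in / (w_in + w_bound + penalty)`, or 0 when the denominator is zero.
#'
#' @param graph an interaction graph.
#' @param members non-empty character vector of member nodes.
#' @param penalty non-negative penalty.
#' @return a number in \[0, 1\].
#' @export
cohesiveness <- function(graph, members, penalty = 2) {
  members <- check_members(graph, members)
  stopifnot(length(members) > 0, penalty >= 0)
  ends <- igraph::as_edgelist(graph)
  w <- edge_weights(graph)
  if (nrow(ends) == 0) return(0)
  in1 <- ends[, 1] %in% members
  in2 <- ends[, 2] %in% members
  w_in <- sum(w[in1 & in2])
  w_bound <- sum(w[xor(in1, in2)])
  denom <- w_in + w_bound + penalty
  if (denom <= 0) 0 else w_in / denom
}

#' @keywords internal
#' @noRd
internal_density <- function(graph, members) {
  k <- length(members)
  if (k < 2) return(0)
  m <- igraph::ecount(igraph::induced_subgraph(graph, members))
  m / (k * (k - 1) / 2)
}

# --- greedy growth engine (index based, incremental bookkeeping) -----------

#' @keywords internal
#' @noRd
grow_engine <- function(adj_idx, adj_w, wdeg, vnames, seed_idx, penalty,
                        tol = 1e-12) {
  n <- length(vnames)
  w2c <- numeric(n)       # weight from each node to current members
  in_c <- logical(n)
  coh <- function(wi, wb) {
    d <- wi + wb + penalty
    if (d <= 0) 0 else wi / d
  }
  add_node <- function(v) {
    in_c[v] <<- TRUE
    nb <- adj_idx[[v]]
    if (length(nb)) w2c[nb] <<- w2c[nb] + adj_w[[v]]
  }
  drop_node <- function(v) {
    in_c[v] <<- FALSE
    nb <- adj_idx[[v]]
    if (length(nb)) w2c[nb] <<- w2c[nb] - adj_w[[v]]
  }
  add_node(seed_idx)
  w_in <- 0
  w_bound <- wdeg[seed_idx]
  cur <- coh(w_in, w_bound)
  repeat {
    members <- which(in_c)
    cand <- which(!in_c & w2c > 0)
    # deterministic scan: additions then removals, each in byte order of id
    cand <- cand[order(vnames[cand], method = "radix")]
    best <- cur + tol
    best_v <- 0L
    best_add <- TRUE
    for (v in cand) {
      wv <- w2c[v]
      f <- coh(w_in + wv, w_bound - wv + (wdeg[v] - wv))
      if (f > best) { best <- f; best_v <- v; best_add <- TRUE }
    }
    if (length(members) > 1) {
      mem <- members[order(vnames[members], method = "radix")]
      for (v in mem) {
        wv <- w2c[v] # edges from other members to v
        f <- coh(w_in - wv, w_bound - (wdeg[v] - wv) + wv)
        if (f > best) { best <- f; best_v <- v; best_add <- FALSE }
      }
    }
    if (best_v == 0L) break
    wv <- w2c[best_v]
    if (best_add) {
      add_node(best_v)
      w_in <- w_in + wv
      w_bound <- w_bound - wv + (wdeg[best_v] - wv)
    } else {
      drop_node(best_v)
      w_in <- w_in - wv
      w_bound <- w_bound - (wdeg[best_v] - wv) + wv
    }
    cur <- coh(w_in, w_bound)
  }
  list(members = which(in_c), cohesiveness = cur)
}

#' @keywords internal
#' @noRd
graph_engine_data <- function(graph) {
  vnames <- igraph::V(graph)$name
  n <- length(vnames)
  ends <- igraph::as_edgelist(graph, names = FALSE)
  w <- edge_weights(graph)
  adj_idx <- vector("list", n)
  adj_w <- vector("list", n)
  if (nrow(ends) > 0) {
    df <- rbind(cbind(ends[, 1], ends[, 2]), cbind(ends[, 2], ends[, 1]))
    ww <- c(w, w)
    sp <- split(seq_len(nrow(df)), df[, 1])
    for (k in names(sp)) {
      i <- as.integer(k)
      adj_idx[[i]] <- df[sp[[k]], 2]
      adj_w[[i]] <- ww[sp[[k]]]
    }
  }
  for (i in seq_len(n)) {
    if (is.null(adj_idx[[i]])) {
      adj_idx[[i]] <- integer(0)
      adj_w[[i]] <- numeric(0)
    }
  }
  wdeg <- vapply(adj_w, sum, numeric(1))
  list(vnames = vnames, adj_idx = adj_idx, adj_w = adj_w, wdeg = wdeg)
}

#' Grow one cluster from a seed node
#'
#' Starting from `{seed}`, repeatedly applies the single best move -- adding
#' an external node adjacent to the cluster, or removing a member -- that
#' strictly increases cohesiveness, stopping at a local maximum. Candidate
#' moves are scanned deterministically (additions before removals, node ids
#' in byte order, first best kept), so the result is reproducible. Note that
#' the seed itself may be removed along the way.
#'
#' @param graph an interaction graph.
#' @param seed a node identifier present in the graph.
#' @param params a [cluster_params()].
#' @return an object of class `ppi_cluster`: list with sorted `members`,
#'   `cohesiveness`, `density` and Mann-Whitney `p_value` (1 for clusters of
#'   fewer than 2 members).
#' @export
grow_cluster <- function(graph, seed, params = cluster_params()) {
  seed <- check_members(graph, seed)
  stopifnot(length(seed) == 1)
  ed <- graph_engine_data(graph)
  res <- grow_engine(ed$adj_idx, ed$adj_w, ed$wdeg, ed$vnames,
                     match(seed, ed$vnames), params$penalty)
  new_cluster(graph, sort(ed$vnames[res$members], method = "radix"),
              res$cohesiveness)
}

#' @keywords internal
#' @noRd
new_cluster <- function(graph, members, coh) {
  structure(list(
    members = members,
    cohesiveness = coh,
    density = internal_density(graph, members),
    p_value = if (length(members) >= 2) cluster_significance(graph, members)
              else 1
  ), class = "ppi_cluster")
}

#' @export
print.ppi_cluster <- function(x, ...) {
  cat(sprintf("Cluster: %d members, cohesiveness %.4g, density %.4g, p = %.4g\n",
              length(x$members), x$cohesiveness, x$density, x$p_value))
  invisible(x)
}

# --- significance -----------------------------------------------------------

#' One-sided Mann-Whitney p-value (in-weights greater than out-weights)
#'
#' @keywords internal
#' @noRd
mwu_greater_p <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  r_obs <- sum(r[seq_len(n1)])
  if (n1 <= exact_max && n2 <= exact_max) {
    combos <- utils::combn(n1 + n2, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    return(mean(sums >= r_obs - 1e-9))
  }
  n <- n1 + n2
  u <- r_obs - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u - mu - 0.5) / sqrt(sigma2) # continuity-corrected
  p <- stats::pnorm(z, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}

#' Cluster significance (one-sided Mann-Whitney U test)
#'
#' Compares, over the cluster members, each member's total edge weight to
#' other members (in-weight) against its total edge weight to the rest of the
#' graph (out-weight), one-sided for in > out. Exact by permutation
#' enumeration when the cluster has at most 8 members (at most 8 observations
#' per side); tie-corrected, continuity-corrected normal approximation
#' otherwise.
#'
#' @param graph an interaction graph.
#' @param members at least 2 member node ids.
#' @return p-value in (0, 1\].
#' @export
cluster_significance <- function(graph, members) {
  members <- check_members(graph, members)
  if (length(members) < 2) stop("cluster significance needs at least 2 members")
  ends <- igraph::as_edgelist(graph)
  w <- edge_weights(graph)
  in_w <- stats::setNames(numeric(length(members)), members)
  out_w <- in_w
  if (nrow(ends) > 0) {
    m1 <- ends[, 1] %in% members
    m2 <- ends[, 2] %in% members
    acc <- function(vec, nodes, wt) {
      if (length(nodes)) {
        s <- tapply(wt, nodes, sum)
        vec[names(s)] <- vec[names(s)] + as.numeric(s)
      }
      vec
    }
    both <- m1 & m2
    in_w <- acc(in_w, c(ends[both, 1], ends[both, 2]), c(w[both], w[both]))
    out_w <- acc(out_w, ends[m1 & !m2, 1], w[m1 & !m2])
    out_w <- acc(out_w, ends[!m1 & m2, 2], w[!m1 & m2])
  }
  mwu_greater_p(as.numeric(in_w), as.numeric(out_w))
}

# --- full detection ---------------------------------------------------------

#' Match coefficient between two node sets
#'
#' `omega(A, B) = |A n B|^2 / (|A| |B|)`.
#' @keywords internal
#' @noRd
match_coefficient <- function(a, b) {
  length(intersect(a, b))^2 / (length(a) * length(b))
}

#' Detect significant overlapping clusters
#'
#' Grows a cluster from every node, in degree-descending seed order (node id
#' as tie-break), skipping seeds already covered by a previously grown
#' cluster. Identical clusters are deduplicated; cluster pairs with match
#' coefficient `omega >= overlap_omega` are merged (union) iteratively until
#' stable; finally clusters violating `min_size`, `min_density` or the
#' significance threshold are discarded. Output is sorted by size descending,
#' then p-value ascending, then member list.
#'
#' @param graph an interaction graph.
#' @param params a [cluster_params()].
#' @return an object of class `ppi_cluster_set`: list of `ppi_cluster`.
#' @export
find_clusters <- function(graph, params = cluster_params()) {
  ed <- graph_engine_data(graph)
  n <- length(ed$vnames)
  if (n == 0) return(structure(list(), class = "ppi_cluster_set",
                               params = params))
  deg <- lengths(ed$adj_idx)
  seeds <- order(-deg, ed$vnames, method = "radix")
  covered <- logical(n)
  grown <- list()
  seen <- new.env(parent = emptyenv())
  for (s in seeds) {
    if (covered[s]) next
    res <- grow_engine(ed$adj_idx, ed$adj_w, ed$wdeg, ed$vnames, s,
                       params$penalty)
    covered[res$members] <- TRUE
    covered[s] <- TRUE
    mem <- sort(ed$vnames[res$members], method = "radix")
    key <- paste(mem, collapse = "\r")
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    grown[[length(grown) + 1L]] <- mem
  }
  # iterative overlap merging
  repeat {
    merged <- FALSE
    k <- length(grown)
    if (k >= 2) {
      for (i in seq_len(k - 1)) {
        for (j in seq.int(i + 1, k)) {
          if (match_coefficient(grown[[i]], grown[[j]]) >=
              params$overlap_omega) {
            grown[[i]] <- sort(union(grown[[i]], grown[[j]]),
                               method = "radix")
            grown[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  # dedupe after merging, then score and filter
  keys <- vapply(grown, paste, character(1), collapse = "\r")
  grown <- grown[!duplicated(keys)]
  clusters <- lapply(grown, function(mem) {
    new_cluster(graph, mem, cohesiveness(graph, mem, params$penalty))
  })
  keep <- vapply(clusters, function(cl) {
    length(cl$members) >= params$min_size &&
      cl$density >= params$min_density &&
      cl$p_value <= params$p_threshold
  }, logical(1))
  clusters <- clusters[keep]
  if (length(clusters)) {
    sz <- vapply(clusters, function(cl) length(cl$members), numeric(1))
    pv <- vapply(clusters, function(cl) cl$p_value, numeric(1))
    ms <- vapply(clusters, function(cl) paste(cl$members, collapse = ","),
                 character(1))
    clusters <- clusters[order(-sz, pv, ms, method = "radix")]
  }
  structure(clusters, class = "ppi_cluster_set", params = params)
}

#' @export
print.ppi_cluster_set <- function(x, ...) {
  cat(sprintf("%d significant cluster(s)\n", length(x)))
  for (cl in x) print(cl)
  invisible(x)
}

#' Cluster set as a data frame
#'
#' One row per cluster: `size`, `cohesiveness`, `density`, `p_value` and the
#' comma-joined `members`.
#'
#' @param x a `ppi_cluster_set`.
#' @param ... unused.
#' @return data frame.
#' @export
as.data.frame.ppi_cluster_set <- function(x, ...) {
  data.frame(
    size = vapply(x, function(cl) length(cl$members), integer(1)),
    cohesiveness = vapply(x, function(cl) cl$cohesiveness, numeric(1)),
    density = vapply(x, function(cl) cl$density, numeric(1)),
    p_value = vapply(x, function(cl) cl$p_value, numeric(1)),
    members = vapply(x, function(cl) paste(cl$members, collapse = ","),
                     character(1)),
    stringsAsFactors = FALSE
  )
}
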