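# Generic term enrichment over user-supplied annotation tables: one-sided
# hypergeometric tests with multiple-testing correction, plus Cohen's-kappa
# grouping of redundant terms (terms annotating nearly the same genes end up
# in the same group), in the style of kappa-based GO/KEGG grouping tools.

#' Build an annotation set
#'
#' @param term_to_genes named list: term id -> character vector of annotated
#'   genes. Terms must be non-empty and annotate only universe genes.
#' @param universe character vector of all analyzable gene ids.
#' @param term_names optional named character vector mapping term ids to
#'   human-readable labels.
#' @return an `annotation_set` list.
#' @export
annotation_set <- function(term_to_genes, universe, term_names = NULL) {
  stopifnot(is.list(term_to_genes), length(universe) > 0)
  universe <- sort(unique(as.character(universe)), method = "radix")
  term_to_genes <- lapply(term_to_genes, function(g)
    sort(unique(as.character(g)), method = "radix"))
  if (is.null(names(term_to_genes)) || any(!nzchar(names(term_to_genes)))) {
    stop("`term_to_genes` must be a named list")
  }
  if (any(lengths(term_to_genes) == 0)) stop("empty terms are not allowed")
  stray <- setdiff(unique(unlist(term_to_genes)), universe)
  if (length(stray) > 0) {
    stop("annotated gene(s) outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  structure(list(universe = universe, term_to_genes = term_to_genes,
                 term_names = term_names),
            class = "annotation_set")
}

#' Read annotation tables
#'
#' @param path two-column TSV (term_id, gene_id), no header required; a
#'   header line is detected when the first line repeats on no gene.
#' @param names_path optional two-column TSV (term_id, term_name).
#' @param universe optional universe; defaults to all annotated genes.
#' @return an `annotation_set`.
#' @export
read_annotations <- function(path, names_path = NULL, universe = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           col.names = c("term", "gene"))
  term_to_genes <- split(tab$gene, tab$term)
  term_names <- NULL
  if (!is.null(names_path)) {
    nm <- utils::read.table(names_path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, quote = "")
    term_names <- stats::setNames(as.character(nm[[2]]), nm[[1]])
  }
  if (is.null(universe)) universe <- unique(tab$gene)
  annotation_set(term_to_genes, universe, term_names)
}

#' Hypergeometric enrichment p-value (right tail)
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of seeing
#' at least `k` annotated genes in a query of size `n` drawn from a universe
#' of `N` genes of which `K` carry the term.
#'
#' @param k observed query hits.
#' @param n query size.
#' @param K term size.
#' @param N universe size.
#' @return p-value in (0, 1\].
#' @export
hypergeom_p <- function(k, n, K, N) {
  if (!(k >= 0 && k <= min(n, K) && min(n, K) <= N && n <= N && K <= N)) {
    stop("require 0 <= k <= min(n, K) <= N")
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Cohen's kappa between two terms' gene memberships
#'
#' Chance-corrected agreement of the two binary membership vectors over the
#' universe. With `a = |A n B|`, `b = |A \ B|`, `c = |B \ A|` and
#' `d = N - a - b - c`: observed agreement `po = (a + d) / N`, expected
#' agreement `pe = ((a+b)(a+c) + (c+d)(b+d)) / N^2`, kappa
#' `(po - pe) / (1 - pe)` (1 when `pe = 1`).
#'
#' @param term_a,term_b character vectors of genes, subsets of `universe`.
#' @param universe character vector of all genes.
#' @return kappa in \[-1, 1\].
#' @export
kappa_score <- function(term_a, term_b, universe) {
  stopifnot(length(universe) > 0)
  n <- length(unique(universe))
  a <- length(intersect(term_a, term_b))
  b <- length(setdiff(term_a, term_b))
  cc <- length(setdiff(term_b, term_a))
  d <- n - a - b - cc
  po <- (a + d) / n
  pe <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / n^2
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

#' @keywords internal
#' @noRd
kappa_groups <- function(term_sets, universe, kappa_threshold) {
  terms <- names(term_sets)
  nt <- length(terms)
  parent <- seq_len(nt)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nt >= 2) {
    for (i in seq_len(nt - 1)) {
      for (j in seq.int(i + 1, nt)) {
        if (kappa_score(term_sets[[i]], term_sets[[j]], universe) >=
            kappa_threshold) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  comp <- vapply(seq_len(nt), find, integer(1))
  groups <- split(terms, comp)
  # merge groups sharing at least half of the smaller group's terms
  # (connected components are disjoint, so this loop is a stable no-op
  # unless callers supply pre-made overlapping groups)
  repeat {
    merged <- FALSE
    k <- length(groups)
    if (k >= 2) {
      for (i in seq_len(k - 1)) {
        for (j in seq.int(i + 1, k)) {
          shared <- length(intersect(groups[[i]], groups[[j]]))
          if (shared >= 0.5 * min(length(groups[[i]]), length(groups[[j]])) &&
              shared > 0) {
            groups[[i]] <- union(groups[[i]], groups[[j]])
            groups[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  groups
}

#' Term enrichment with kappa grouping
#'
#' Tests every term with at least one query hit by the right-tailed
#' hypergeometric test, adjusts p-values over all tested terms, and groups
#' redundant terms: a term graph is built with an edge wherever the kappa
#' score of two terms reaches `kappa_threshold`, initial groups are its
#' connected components, and groups sharing at least half of the smaller
#' group's terms are merged until stable. Group labels are contiguous from 1,
#' ordered by each group's best adjusted p-value.
#'
#' Query genes absent from the universe are dropped with a warning.
#'
#' @param query character vector of query gene ids (e.g. a cluster's members).
#' @param ann an [annotation_set()].
#' @param correction `"bh"` (Benjamini-Hochberg, default) or `"bonferroni"`.
#' @param kappa_threshold kappa at or above which two terms are connected
#'   (default 0.4).
#' @return data frame with one row per tested term: `term`, `name`, `k`
#'   (query hits), `K` (term size), `n` (query size), `N` (universe size),
#'   `p_value`, `p_adjusted`, `group`; sorted by (group, p_adjusted, term).
#' @export
enrich <- function(query, ann, correction = c("bh", "bonferroni"),
                   kappa_threshold = 0.4) {
  correction <- match.arg(correction)
  stopifnot(inherits(ann, "annotation_set"))
  query <- unique(as.character(query))
  if (length(query) == 0) stop("empty query")
  outside <- setdiff(query, ann$universe)
  if (length(outside) > 0) {
    warning(sprintf("dropped %d query gene(s) not in the universe",
                    length(outside)))
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) stop("no query genes left inside the universe")
  n <- length(query)
  N <- length(ann$universe)
  hits <- vapply(ann$term_to_genes, function(g)
    length(intersect(query, g)), integer(1))
  tested <- names(hits)[hits >= 1]
  if (length(tested) == 0) {
    return(data.frame(term = character(), name = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      p_value = numeric(), p_adjusted = numeric(),
                      group = integer(), stringsAsFactors = FALSE))
  }
  tested <- sort(tested, method = "radix")
  k <- hits[tested]
  K <- lengths(ann$term_to_genes[tested])
  p <- vapply(tested, function(t) hypergeom_p(hits[[t]], n,
                                              length(ann$term_to_genes[[t]]),
                                              N), numeric(1))
  p_adj <- stats::p.adjust(p, method = if (correction == "bh") "BH"
                                       else "bonferroni")
  groups <- kappa_groups(ann$term_to_genes[tested], ann$universe,
                         kappa_threshold)
  # order groups by best adjusted p, tie-break on the first term id
  best_p <- vapply(groups, function(g) min(p_adj[match(g, tested)]),
                   numeric(1))
  first_term <- vapply(groups, function(g) sort(g, method = "radix")[1],
                       character(1))
  groups <- groups[order(best_p, first_term, method = "radix")]
  group_of <- stats::setNames(rep(seq_along(groups), lengths(groups)),
                              unlist(groups))
  nm <- if (is.null(ann$term_names)) rep(NA_character_, length(tested)) else
    unname(ann$term_names[tested])
  out <- data.frame(term = tested, name = nm, k = as.integer(k),
                    K = as.integer(K), n = n, N = N, p_value = p,
                    p_adjusted = p_adj,
                    group = as.integer(group_of[tested]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$group, out$p_adjusted, out$term, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Kappa edges between tested terms
#'
#' Term-network edge list for the groups reported by [enrich()]: all term
#' pairs whose kappa score reaches the threshold.
#'
#' @param ann an [annotation_set()].
#' @param terms term ids to consider (default: all terms of `ann`).
#' @param kappa_threshold minimum kappa for an edge.
#' @return data frame with `term_a`, `term_b`, `kappa`, sorted.
#' @export
kappa_edges <- function(ann, terms = names(ann$term_to_genes),
                        kappa_threshold = 0.4) {
  terms <- sort(intersect(terms, names(ann$term_to_genes)), method = "radix")
  res <- list()
  nt <- length(terms)
  if (nt >= 2) {
    for (i in seq_len(nt - 1)) {
      for (j in seq.int(i + 1, nt)) {
        kp <- kappa_score(ann$term_to_genes[[terms[i]]],
                          ann$term_to_genes[[terms[j]]], ann$universe)
        if (kp >= kappa_threshold) {
          res[[length(res) + 1L]] <- data.frame(
            term_a = terms[i], term_b = terms[j], kappa = kp,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(term_a = character(), term_b = character(),
                      kappa = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, res)
}
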