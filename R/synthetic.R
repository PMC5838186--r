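# Seeded synthetic benchmarks with the statistical structure a disease
# interactome analysis assumes: a scale-free main component, a handful of
# super-connected (planted hub) nodes, planted cliques attached by a single
# bridge, isolated and paired nodes, and annotation tables with one planted
# enriched term. Every planted feature is returned as ground truth so each
# downstream stage can be validated.

#' Specification of a synthetic benchmark
#'
#' Defaults emulate the shape of a STRING disease-query interactome of a few
#' hundred genes: a 600-node preferential-attachment core (2 edges per new
#' node), 5 planted hubs each wired to a uniform random 30 percent of the
#' core, three planted 8-cliques each tied to the core by one bridge edge,
#' 145 isolated nodes and one isolated pair.
#'
#' @param n_core nodes in the scale-free core (0, or more than `attach_m`).
#' @param attach_m preferential-attachment edges per new core node.
#' @param planted_hubs number of planted super-connected nodes.
#' @param hub_attach_frac fraction of the core each planted hub is wired to.
#' @param planted_cliques data frame (or list coercible to one) with columns
#'   `size` (>= 3) and `count`.
#' @param n_isolated number of isolated singleton nodes.
#' @param n_paired number of nodes living in isolated pairs (must be even).
#' @param n_terms number of random annotation terms.
#' @param term_size_range inclusive range of random term sizes.
#' @param planted_term_overlap fraction of the planted hubs covered by the
#'   planted annotation term.
#' @param seed integer random seed (mandatory; the whole benchmark is a pure
#'   function of this spec).
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_core = 600, attach_m = 2, planted_hubs = 5,
                           hub_attach_frac = 0.3,
                           planted_cliques = data.frame(size = 8, count = 3),
                           n_isolated = 145, n_paired = 2,
                           n_terms = 50, term_size_range = c(5, 50),
                           planted_term_overlap = 1.0, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  planted_cliques <- as.data.frame(planted_cliques)
  if (nrow(planted_cliques) > 0) {
    stopifnot(all(c("size", "count") %in% names(planted_cliques)),
              all(planted_cliques$size >= 3), all(planted_cliques$count >= 0))
  }
  stopifnot(n_core >= 0, attach_m >= 1, planted_hubs >= 0,
            hub_attach_frac > 0, hub_attach_frac <= 1,
            n_isolated >= 0, n_paired >= 0, n_paired %% 2 == 0,
            n_terms >= 0, length(term_size_range) == 2,
            term_size_range[1] >= 1, term_size_range[2] >= term_size_range[1],
            planted_term_overlap >= 0, planted_term_overlap <= 1)
  if (planted_hubs > 0 && n_core == 0) {
    stop("planted hubs require a non-empty core")
  }
  if (n_core > 0 && n_core <= attach_m) {
    stop("`n_core` must exceed `attach_m` (or be 0)")
  }
  structure(list(n_core = n_core, attach_m = attach_m,
                 planted_hubs = planted_hubs,
                 hub_attach_frac = hub_attach_frac,
                 planted_cliques = planted_cliques,
                 n_isolated = n_isolated, n_paired = n_paired,
                 n_terms = n_terms, term_size_range = term_size_range,
                 planted_term_overlap = planted_term_overlap,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random annotation tables with one planted term
#'
#' Draws `n_terms` random terms (sizes uniform in `size_range`) over the
#' universe and, when `planted_genes` is given, adds a term `planted_term`
#' annotating exactly those genes.
#'
#' @param universe character vector of gene ids.
#' @param n_terms number of random terms.
#' @param size_range inclusive range of term sizes.
#' @param planted_genes genes of the planted term (or `NULL` for none).
#' @param planted_term id of the planted term.
#' @param seed integer random seed.
#' @return an [annotation_set()].
#' @export
make_annotations <- function(universe, n_terms, size_range = c(5, 50),
                             planted_genes = NULL,
                             planted_term = "TERM_PLANTED", seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  universe <- sort(unique(as.character(universe)), method = "radix")
  with_seed(seed, {
    sizes <- sample(seq.int(size_range[1], size_range[2]), n_terms,
                    replace = TRUE)
    sizes <- pmin(sizes, length(universe))
    term_to_genes <- lapply(sizes, function(s) sample(universe, s))
    names(term_to_genes) <- sprintf("TERM_%04d", seq_len(n_terms))
    if (!is.null(planted_genes) && length(planted_genes) > 0) {
      term_to_genes[[planted_term]] <- unique(as.character(planted_genes))
    }
    term_names <- stats::setNames(
      paste("annotation", names(term_to_genes)), names(term_to_genes))
    annotation_set(term_to_genes, universe, term_names)
  })
}

#' Generate a synthetic benchmark
#'
#' Assembles the graph described by a [synthetic_spec()] plus ground truth:
#' a preferential-attachment core (`G0001`, ...), planted hubs (`HUB1`, ...)
#' each wired to a uniform random fraction of the core, planted cliques
#' (`CLQ<i>_<j>`) attached to the core by exactly one bridge edge, isolated
#' singletons (`ISO...`) and disjoint pairs (`PRD...a/b`). Edge confidence
#' scores are drawn uniform on \[0.6, 1\] and rounded to 3 decimals (all
#' above the conventional 0.4 STRING cutoff, so writing and re-reading the
#' benchmark reproduces the same graph). Annotations consist of random terms
#' plus one planted term covering the requested fraction of the planted hubs.
#' All randomness derives from the single seed in the spec; the same spec
#' always yields the identical benchmark.
#'
#' @param spec a [synthetic_spec()].
#' @return a `ppi_benchmark` list: `graph`, `truth_hubs`, `truth_cliques`
#'   (list of member vectors), `annotations`, `truth_term`, `spec`.
#' @export
make_benchmark <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    core_names <- if (spec$n_core > 0) sprintf("G%04d", seq_len(spec$n_core))
                  else character(0)
    edges_from <- character(0)
    edges_to <- character(0)
    if (spec$n_core > 0) {
      core <- igraph::sample_pa(spec$n_core, power = 1, m = spec$attach_m,
                                directed = FALSE)
      el <- igraph::as_edgelist(core, names = FALSE)
      edges_from <- core_names[el[, 1]]
      edges_to <- core_names[el[, 2]]
    }
    truth_hubs <- character(0)
    if (spec$planted_hubs > 0) {
      truth_hubs <- sprintf("HUB%d", seq_len(spec$planted_hubs))
      n_attach <- max(1L, round(spec$hub_attach_frac * spec$n_core))
      for (h in truth_hubs) {
        targets <- sample(core_names, n_attach)
        edges_from <- c(edges_from, rep(h, n_attach))
        edges_to <- c(edges_to, targets)
      }
    }
    truth_cliques <- list()
    if (nrow(spec$planted_cliques) > 0) {
      idx <- 0L
      for (r in seq_len(nrow(spec$planted_cliques))) {
        sz <- spec$planted_cliques$size[r]
        for (cnt in seq_len(spec$planted_cliques$count[r])) {
          idx <- idx + 1L
          mem <- sprintf("CLQ%d_%d", idx, seq_len(sz))
          pairs <- utils::combn(mem, 2)
          edges_from <- c(edges_from, pairs[1, ])
          edges_to <- c(edges_to, pairs[2, ])
          if (length(core_names) > 0) { # one bridge into the core
            edges_from <- c(edges_from, mem[1])
            edges_to <- c(edges_to, sample(core_names, 1))
          }
          truth_cliques[[idx]] <- mem
        }
      }
    }
    iso_names <- if (spec$n_isolated > 0)
      sprintf("ISO%03d", seq_len(spec$n_isolated)) else character(0)
    pair_names <- character(0)
    if (spec$n_paired > 0) {
      for (p in seq_len(spec$n_paired / 2)) {
        a <- sprintf("PRD%02da", p)
        b <- sprintf("PRD%02db", p)
        edges_from <- c(edges_from, a)
        edges_to <- c(edges_to, b)
        pair_names <- c(pair_names, a, b)
      }
    }
    weights <- round(stats::runif(length(edges_from), 0.6, 1), 3)
    graph <- ppi_graph(
      data.frame(from = edges_from, to = edges_to, weight = weights,
                 stringsAsFactors = FALSE),
      nodes = c(core_names, iso_names, pair_names),
      name = sprintf("synthetic benchmark (seed %d)", spec$seed)
    )
    n_covered <- round(spec$planted_term_overlap * length(truth_hubs))
    planted_genes <- if (n_covered > 0) truth_hubs[seq_len(n_covered)] else
      NULL
    annotations <- if (spec$n_terms > 0 || !is.null(planted_genes)) {
      make_annotations(igraph::V(graph)$name, spec$n_terms,
                       spec$term_size_range, planted_genes,
                       seed = spec$seed + 1L)
    } else NULL
    structure(list(graph = graph, truth_hubs = truth_hubs,
                   truth_cliques = truth_cliques, annotations = annotations,
                   truth_term = if (is.null(planted_genes)) NA_character_
                                else "TERM_PLANTED",
                   spec = spec),
              class = "ppi_benchmark")
  })
}

#' @export
print.ppi_benchmark <- function(x, ...) {
  cat(sprintf(
    "Synthetic benchmark (seed %d): %d nodes, %d edges, %d planted hub(s), %d planted clique(s)\n",
    x$spec$seed, igraph::vcount(x$graph), igraph::ecount(x$graph),
    length(x$truth_hubs), length(x$truth_cliques)))
  invisible(x)
}

#' Write a benchmark to disk
#'
#' Emits the STRING-style edge list (scores on the 0-1000 scale), the
#' annotation and term-name TSVs, and the ground truth as JSON, so the
#' benchmark exercises the package's real file readers.
#'
#' @param benchmark a `ppi_benchmark`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- benchmark$graph
  ends <- igraph::as_edgelist(g)
  w <- edge_weights(g)
  lo <- pmin(ends[, 1], ends[, 2])
  hi <- pmax(ends[, 1], ends[, 2])
  ord <- order(lo, hi, method = "radix")
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  lines <- c("node1\tnode2\tcombined_score",
             sprintf("%s\t%s\t%d", lo[ord], hi[ord],
                     as.integer(round(w[ord] * 1000))))
  writeLines(lines, file.path(dir, "network.tsv"))
  # an edge list cannot carry isolated nodes; the full node list rides along
  writeLines(sort(igraph::V(g)$name, method = "radix"),
             file.path(dir, "nodes.txt"))
  if (!is.null(benchmark$annotations)) {
    ann <- benchmark$annotations
    rows <- unlist(lapply(sort(names(ann$term_to_genes), method = "radix"),
                          function(t) sprintf("%s\t%s", t,
                                              ann$term_to_genes[[t]])))
    writeLines(rows, file.path(dir, "annotations.tsv"))
    if (!is.null(ann$term_names)) {
      nm <- sort(names(ann$term_names), method = "radix")
      writeLines(sprintf("%s\t%s", nm, ann$term_names[nm]),
                 file.path(dir, "term_names.tsv"))
    }
  }
  truth <- list(hubs = benchmark$truth_hubs,
                cliques = benchmark$truth_cliques,
                term = benchmark$truth_term)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
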