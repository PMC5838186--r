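# construction used in several blocks: two K4 cliques joined by one bridge
two_k4 <- function() {
  a <- sprintf("a%d", 1:4)
  b <- sprintf("b%d", 1:4)
  g <- ppi_graph(rbind(clique_df(a), clique_df(b), edges_df("a1", "b1")))
  list(g = g, a = a, b = b)
}

test_that("cohesiveness follows w_in / (w_in + w_bound + penalty)", {
  tri <- ppi_graph(rbind(clique_df(c("a", "b", "c")), edges_df("d", "a")))
  expect_equal(cohesiveness(tri, c("a", "b", "c"), penalty = 0), 0.75)
  expect_equal(cohesiveness(tri, c("a", "b", "c", "d"), penalty = 0), 1)

  tk <- two_k4()
  expect_equal(cohesiveness(tk$g, tk$a, penalty = 2), 6 / 9)

  expect_error(cohesiveness(tk$g, c("a1", "nope")), "nope")
})

test_that("cohesiveness is monotone in internal edges and antitone in the penalty", {
  set.seed(8)
  for (i in 1:20) {
    g <- rand_ppi_graph(7, 0.4)
    vn <- igraph::V(g)$name
    mem <- sample(vn, 4)
    f <- cohesiveness(g, mem, penalty = 2)
    expect_gte(f, 0); expect_lte(f, 1)
    expect_lte(cohesiveness(g, mem, penalty = 3), f + 1e-12)
    inside <- utils::combn(mem, 2)
    absent <- inside[, !apply(inside, 2, function(p)
      igraph::are_adjacent(g, p[1], p[2])), drop = FALSE]
    if (ncol(absent) > 0) {
      g2 <- igraph::add_edges(g, absent[, 1], weight = 1)
      expect_gte(cohesiveness(g2, mem, penalty = 2), f - 1e-12)
    }
  }
})

test_that("greedy growth stops at the seed clique when the bridge hurts cohesiveness", {
  tk <- two_k4()
  cl <- grow_cluster(tk$g, "a2", cluster_params(penalty = 2))
  expect_setequal(cl$members, tk$a)
  expect_equal(cl$cohesiveness, 6 / 9, tolerance = 1e-12)
  expect_equal(cl$density, 1)
})

test_that("growth handles isolated seeds and saturates whole components", {
  g <- ppi_graph(clique_df(sprintf("k%d", 1:5)), nodes = "lone")
  cl <- grow_cluster(g, "lone")
  expect_equal(cl$members, "lone")
  expect_equal(cl$cohesiveness, 0)

  cl2 <- grow_cluster(g, "k3", cluster_params(penalty = 0))
  expect_setequal(cl2$members, sprintf("k%d", 1:5))
  expect_equal(cl2$cohesiveness, 1)
})

test_that("every returned cluster is a local maximum of cohesiveness", {
  set.seed(13)
  for (i in 1:10) {
    g <- rand_ppi_graph(sample(5:7, 1), stats::runif(1, 0.3, 0.8))
    vn <- igraph::V(g)$name
    cl <- grow_cluster(g, sample(vn, 1), cluster_params(penalty = 1))
    f0 <- cohesiveness(g, cl$members, penalty = 1)
    expect_equal(f0, cl$cohesiveness, tolerance = 1e-12)
    for (v in setdiff(vn, cl$members)) {
      expect_lte(cohesiveness(g, c(cl$members, v), penalty = 1), f0 + 1e-9)
    }
    if (length(cl$members) > 1) {
      for (v in cl$members) {
        expect_lte(cohesiveness(g, setdiff(cl$members, v), penalty = 1),
                   f0 + 1e-9)
      }
    }
  }
})

test_that("exact Mann-Whitney p-values match exhaustive permutation enumeration", {
  # the fully separated 3-vs-3 case: only 1 of C(6,3)=20 assignments as extreme
  expect_equal(ppinet:::mwu_greater_p(c(3, 3, 3), c(0, 0, 0)), 0.05)

  set.seed(17)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(0:4, n1, replace = TRUE) # ties included on purpose
    y <- sample(0:4, n2, replace = TRUE)
    expect_equal(ppinet:::mwu_greater_p(x, y), oracle_mwu_greater(x, y),
                 tolerance = 1e-12)
  }
})

test_that("the normal-approximation branch tracks the classical corrected test", {
  set.seed(19)
  for (i in 1:10) {
    x <- stats::rnorm(12, mean = 1)
    y <- stats::rnorm(12)
    p <- ppinet:::mwu_greater_p(x, y)
    ref <- stats::wilcox.test(x, y, alternative = "greater", exact = FALSE,
                              correct = TRUE)$p.value
    expect_equal(p, ref, tolerance = 1e-9)
  }
})

test_that("cluster significance separates dense modules from their boundary", {
  g <- ppi_graph(clique_df(c("x", "y", "z")), nodes = "w")
  expect_equal(cluster_significance(g, c("x", "y", "z")), 0.05)
  expect_error(cluster_significance(g, "x"), "at least 2")

  # in-weights equal to out-weights elementwise: no separation
  g2 <- ppi_graph(edges_df(c("a", "b", "a2", "b2"), c("b", "c", "a", "b")))
  p <- cluster_significance(g2, c("a", "b"))
  expect_gte(p, 0.5)
})

test_that("three planted K6 cliques are recovered exactly on a scattered background", {
  cliques <- lapply(1:3, function(i) sprintf("C%d_%d", i, 1:6))
  bg <- scatter_background(40, 5)
  g <- ppi_graph(rbind(do.call(rbind, lapply(cliques, clique_df)), bg$edges),
                 nodes = bg$nodes)
  # an exact one-sided MWU on 6+6 observations cannot reach p <= 0.001
  # (its floor is 1/choose(12, 6) = 1/924), so the paper-level cutoff is
  # relaxed to 0.05 when probing recovery of 6-cliques
  cls <- find_clusters(g, cluster_params(p_threshold = 0.05))
  expect_length(cls, 3L)
  found <- lapply(cls, `[[`, "members")
  for (cl in cliques) {
    expect_true(any(vapply(found, function(f) setequal(f, cl), logical(1))))
  }
  expect_equal(cls[[1]]$p_value, 1 / 924, tolerance = 1e-12)
  # and at the 0.001 default the same clusters are (necessarily) excluded
  expect_length(find_clusters(g, cluster_params()), 0L)
})

test_that("planted 8-cliques on a scale-free background are recovered at default parameters", {
  b <- make_benchmark(synthetic_spec(n_core = 100, attach_m = 2,
                                     planted_hubs = 0,
                                     planted_cliques = data.frame(size = 8,
                                                                  count = 2),
                                     n_isolated = 10, n_paired = 0,
                                     n_terms = 0, seed = 23))
  cls <- find_clusters(b$graph)
  found <- lapply(cls, `[[`, "members")
  for (cl in b$truth_cliques) {
    expect_gte(max(vapply(found, function(f) jaccard(f, cl), numeric(1))), 0.8)
  }
})

test_that("the match coefficient drives merging and deduplication", {
  expect_equal(ppinet:::match_coefficient(1:4, 3:6), 0.25)
  expect_equal(ppinet:::match_coefficient(1:4, 1:4), 1)

  # two seeds growing to the same clique collapse to a single cluster
  g <- ppi_graph(clique_df(sprintf("k%d", 1:8)),
                 nodes = sprintf("i%02d", 1:10))
  cls <- find_clusters(g, cluster_params(p_threshold = 0.05))
  expect_length(cls, 1L)
  expect_setequal(cls[[1]]$members, sprintf("k%d", 1:8))
})
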