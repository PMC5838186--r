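test_that("assembly-only specs produce exactly the requested components", {
  spec <- synthetic_spec(n_core = 0, planted_hubs = 0,
                         planted_cliques = data.frame(size = integer(),
                                                      count = integer()),
                         n_isolated = 3, n_paired = 2, n_terms = 0, seed = 1)
  b <- make_benchmark(spec)
  expect_equal(igraph::vcount(b$graph), 5L)
  expect_equal(igraph::ecount(b$graph), 1L)
  expect_equal(summarize_graph(b$graph)$component_sizes, c(2L, 1L, 1L, 1L))
})

test_that("the same spec always regenerates the identical benchmark", {
  spec <- synthetic_spec(n_core = 80, planted_hubs = 2,
                         planted_cliques = data.frame(size = 5, count = 1),
                         n_isolated = 5, n_paired = 2, n_terms = 8, seed = 99)
  b1 <- make_benchmark(spec)
  b2 <- make_benchmark(spec)
  expect_identical(igraph::as_edgelist(b1$graph), igraph::as_edgelist(b2$graph))
  expect_identical(igraph::E(b1$graph)$weight, igraph::E(b2$graph)$weight)
  expect_identical(b1$truth_hubs, b2$truth_hubs)
  expect_identical(b1$annotations$term_to_genes, b2$annotations$term_to_genes)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_benchmark(b1, d1)
  write_benchmark(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("generation does not disturb the caller's random stream", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(make_benchmark(synthetic_spec(n_core = 30, planted_hubs = 1,
                                          n_isolated = 0, n_paired = 0,
                                          n_terms = 0, seed = 5)))
  expect_identical(stats::runif(1), before)
})

test_that("paper-scale benchmarks have the expected component anatomy", {
  b <- make_benchmark(synthetic_spec(seed = 7))
  s <- summarize_graph(b$graph)
  expect_equal(s$n_isolated, 145L)
  expect_equal(s$n_paired, 2L)
  # one dominant component holding the core, the hubs and the bridged cliques
  expect_equal(s$component_sizes[1], 600L + 5L + 24L)
  expect_equal(s$n_nodes, 776L)
  expect_true(all(igraph::E(b$graph)$weight > 0 &
                  igraph::E(b$graph)$weight <= 1))
})

test_that("planted hubs occupy the top of the degree ranking", {
  for (seed in 1:5) {
    b <- make_benchmark(synthetic_spec(n_core = 300, planted_hubs = 3,
                                       n_isolated = 20, n_paired = 2,
                                       n_terms = 0, seed = seed))
    d <- degree_all(b$graph)
    top <- names(sort(d, decreasing = TRUE))[1:3]
    expect_setequal(top, b$truth_hubs)
  }
})

test_that("the scale-free core yields a negative power-law exponent", {
  b <- make_benchmark(synthetic_spec(n_core = 400, planted_hubs = 0,
                                     planted_cliques = data.frame(size = integer(),
                                                                  count = integer()),
                                     n_isolated = 0, n_paired = 0,
                                     n_terms = 0, seed = 3))
  fit <- fit_power_law(degree_histogram(b$graph))
  expect_lt(fit$b, 0)
})

test_that("benchmarks survive the round trip through their own file formats", {
  b <- make_benchmark(synthetic_spec(n_core = 60, planted_hubs = 2,
                                     planted_cliques = data.frame(size = 5,
                                                                  count = 1),
                                     n_isolated = 8, n_paired = 2,
                                     n_terms = 6, seed = 42))
  dir <- withr::local_tempdir()
  write_benchmark(b, dir)
  g <- read_string_tsv(file.path(dir, "network.tsv"), 0.4)
  extra <- setdiff(readLines(file.path(dir, "nodes.txt")),
                   igraph::V(g)$name)
  g <- igraph::add_vertices(g, length(extra), name = extra)
  expect_setequal(igraph::V(g)$name, igraph::V(b$graph)$name)
  expect_equal(igraph::ecount(g), igraph::ecount(b$graph))
  key <- function(x) {
    e <- igraph::as_edgelist(x)
    o <- order(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), method = "radix")
    paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]),
          igraph::E(x)$weight)[o]
  }
  expect_identical(key(g), key(b$graph))

  ann <- read_annotations(file.path(dir, "annotations.tsv"),
                          file.path(dir, "term_names.tsv"),
                          universe = igraph::V(b$graph)$name)
  expect_identical(ann$term_to_genes, b$annotations$term_to_genes)
})

test_that("spec validation rejects inconsistent requests", {
  expect_error(synthetic_spec(n_core = 100), "mandatory")
  expect_error(synthetic_spec(n_core = 0, planted_hubs = 2, seed = 1),
               "non-empty core")
  expect_error(synthetic_spec(n_paired = 3, seed = 1))
  expect_error(synthetic_spec(planted_cliques = data.frame(size = 2,
                                                           count = 1),
                              seed = 1))
})
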