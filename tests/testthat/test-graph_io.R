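test_that("STRING edge lists parse with thresholding, deduplication and self-loop removal", {
  tf <- withr::local_tempfile()
  writeLines(c("A\tB\t900", "B\tA\t700", "C\tC\t950", "A\tC\t300"), tf)
  expect_warning(g <- read_string_tsv(tf, 0.4), "self-loop")
  expect_setequal(igraph::V(g)$name, c("A", "B", "C"))
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 0.9) # reversed duplicate kept at max
})

test_that("STRING rows without a score default to weight 1 and scale is auto-detected", {
  tf <- withr::local_tempfile()
  writeLines("A\tB", tf)
  g <- read_string_tsv(tf, 0.9)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$weight, 1.0)

  # unit-scale scores are taken as-is
  tf2 <- withr::local_tempfile()
  writeLines(c("A\tB\t0.95", "B\tC\t0.2"), tf2)
  g2 <- read_string_tsv(tf2, 0.5)
  expect_equal(igraph::ecount(g2), 1L)
  expect_equal(igraph::E(g2)$weight, 0.95)
  expect_setequal(igraph::V(g2)$name, c("A", "B", "C"))
})

test_that("STRING header rows are skipped and empty files give empty graphs", {
  tf <- withr::local_tempfile()
  writeLines(c("node1\tnode2\tcombined_score", "A\tB\t800"), tf)
  g <- read_string_tsv(tf)
  expect_setequal(igraph::V(g)$name, c("A", "B"))
  expect_equal(igraph::ecount(g), 1L)

  tf2 <- withr::local_tempfile()
  writeLines(character(0), tf2)
  g2 <- read_string_tsv(tf2)
  expect_equal(igraph::vcount(g2), 0L)
  expect_equal(igraph::ecount(g2), 0L)
})

test_that("malformed STRING rows raise errors naming the line", {
  tf <- withr::local_tempfile()
  writeLines(c("A\tB\t900", "loner"), tf)
  expect_error(read_string_tsv(tf), "line 2")
  expect_error(suppressWarnings(
    read_string_tsv(file.path(tempdir(), "no-such-file.tsv"))),
    "no-such-file")
})

test_that("raising the score threshold never increases the edge count", {
  set.seed(42)
  tf <- withr::local_tempfile()
  n <- 40
  from <- sprintf("N%02d", sample(n, 200, replace = TRUE))
  to <- sprintf("N%02d", sample(n, 200, replace = TRUE))
  score <- sample(0:1000, 200, replace = TRUE)
  writeLines(sprintf("%s\t%s\t%d", from, to, score), tf)
  counts <- vapply(seq(0, 1, by = 0.1), function(thr) {
    igraph::ecount(suppressWarnings(read_string_tsv(tf, thr)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("SIF files fan out, keep isolated nodes and reject dangling relations", {
  tf <- withr::local_tempfile()
  writeLines(c("A pp B C", "D"), tf)
  g <- read_sif(tf)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D"))
  el <- igraph::as_edgelist(g)
  expect_setequal(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])),
                  c("A B", "A C"))

  tf2 <- withr::local_tempfile()
  writeLines("A pp A", tf2)
  g2 <- suppressWarnings(read_sif(tf2))
  expect_equal(igraph::vcount(g2), 1L)
  expect_equal(igraph::ecount(g2), 0L)

  tf3 <- withr::local_tempfile()
  writeLines("A pp", tf3)
  expect_error(read_sif(tf3), "line 1")
})

test_that("SIF write/read round-trips node and edge sets", {
  set.seed(7)
  for (i in 1:20) {
    g <- rand_ppi_graph(sample(2:7, 1), stats::runif(1, 0.1, 0.9))
    tf <- withr::local_tempfile()
    write_sif(g, tf)
    g2 <- read_sif(tf)
    expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
    el <- function(x) {
      e <- igraph::as_edgelist(x)
      sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
    }
    expect_equal(el(g2), el(g))
  }
})

test_that("graph summaries match direct formula evaluation", {
  k3 <- complete_graph(c("a", "b", "c"))
  s <- summarize_graph(k3)
  expect_equal(s$density, 1)
  expect_equal(s$avg_clustering, 1)
  expect_equal(s$component_sizes, 3L)

  p3 <- path_graph(c("A", "B", "C"))
  s2 <- summarize_graph(p3)
  expect_equal(s2$density, 2 / 3)
  expect_equal(s2$avg_clustering, 0)

  g <- ppi_graph(rbind(clique_df(c("a", "b", "c")), edges_df("E", "F")),
                 nodes = "D")
  s3 <- summarize_graph(g)
  expect_equal(s3$component_sizes, c(3L, 2L, 1L))
  expect_equal(s3$n_isolated, 1L)
  expect_equal(s3$n_paired, 2L)
  expect_equal(s3$density, 4 / 15)

  s4 <- summarize_graph(ppi_graph())
  expect_equal(s4$n_nodes, 0L)
  expect_equal(s4$density, 0)
})

test_that("density and clustering agree with adjacency-matrix triangle counting", {
  set.seed(11)
  for (i in 1:40) {
    g <- rand_ppi_graph(sample(1:7, 1), stats::runif(1))
    s <- summarize_graph(g)
    o <- oracle_summary(g)
    expect_equal(s$density, o$density, tolerance = 1e-12)
    expect_equal(s$avg_clustering, o$avg_clustering, tolerance = 1e-12)
    expect_equal(sum(s$component_sizes), s$n_nodes)
  }
})

test_that("result tables are written deterministically with headers", {
  tab <- data.frame(Name = c("A", "B"), D = c(2L, 1L),
                    BC = c(0.123456789, 0), CC = c(0.5, 1 / 3))
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_tables(tab, f1)
  write_tables(tab, f2)
  expect_length(readLines(f1), 3L) # header + 2 rows
  expect_identical(readLines(f1), readLines(f2))
  expect_match(readLines(f1)[2], "0.123457") # 6 significant digits

  f3 <- withr::local_tempfile()
  write_tables(tab[0, ], f3)
  expect_length(readLines(f3), 1L)
})
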