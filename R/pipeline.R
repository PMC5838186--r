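# End-to-end orchestration: read -> summarize -> centralities -> crucial
# nodes -> clusters -> crucial-subnetwork extraction -> degree fit ->
# enrichment of the main cluster. Every stage materializes a file so each
# result has an inspectable artifact, and the whole run is a pure function of
# (input files, config).

#' Pipeline configuration
#'
#' @param input path to the network file (STRING-style TSV or SIF; the format
#'   is chosen by `input_format`, default by file extension: `.sif` means
#'   SIF, anything else the STRING TSV).
#' @param out_dir output directory.
#' @param input_format `"auto"`, `"string_tsv"` or `"sif"`.
#' @param nodes optional path to a plain-text node list (one id per line)
#'   added to the graph; edge lists cannot carry isolated nodes.
#' @param score_threshold STRING confidence cutoff on the unit scale.
#' @param selection a [selection_criteria()].
#' @param clusters a [cluster_params()].
#' @param annotations optional path to a 2-column annotation TSV.
#' @param term_names optional path to a term-name TSV.
#' @param enrich_target `"largest_cluster"` (the main cluster, default) or
#'   `"crucial"`.
#' @param correction multiple-testing correction for enrichment.
#' @param kappa_threshold kappa grouping threshold for enrichment.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir,
                            input_format = c("auto", "string_tsv", "sif"),
                            nodes = NULL,
                            score_threshold = 0.4,
                            selection = selection_criteria(),
                            clusters = cluster_params(),
                            annotations = NULL, term_names = NULL,
                            enrich_target = c("largest_cluster", "crucial"),
                            correction = c("bh", "bonferroni"),
                            kappa_threshold = 0.4) {
  structure(list(input = input, out_dir = out_dir,
                 input_format = match.arg(input_format), nodes = nodes,
                 score_threshold = score_threshold, selection = selection,
                 clusters = clusters, annotations = annotations,
                 term_names = term_names,
                 enrich_target = match.arg(enrich_target),
                 correction = match.arg(correction),
                 kappa_threshold = kappa_threshold),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; the nested
#' mappings `selection:` and `clusters:` mirror [selection_criteria()] and
#' [cluster_params()].
#'
#' @param path YAML file.
#' @param ... overrides applied on top of the file's values.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  overrides <- list(...)
  y[names(overrides)] <- overrides
  if (!is.null(y$selection)) y$selection <- do.call(selection_criteria,
                                                    y$selection)
  if (!is.null(y$clusters)) y$clusters <- do.call(cluster_params, y$clusters)
  do.call(pipeline_config, y)
}

#' @keywords internal
#' @noRd
read_input_graph <- function(config) {
  fmt <- config$input_format
  if (fmt == "auto") {
    fmt <- if (grepl("\\.sif$", config$input, ignore.case = TRUE)) "sif"
           else "string_tsv"
  }
  g <- if (fmt == "sif") read_sif(config$input)
       else read_string_tsv(config$input, config$score_threshold)
  if (!is.null(config$nodes)) {
    extra <- setdiff(trimws(readLines(config$nodes, warn = FALSE)),
                     c("", igraph::V(g)$name))
    if (length(extra) > 0) g <- igraph::add_vertices(g, length(extra),
                                                     name = extra)
  }
  g
}

#' Run the full analysis pipeline
#'
#' Executes every stage and writes, under `config$out_dir`:
#' `summary.json` (graph summary), `centrality.tsv` (Name/D/BC/CC table),
#' `selection.tsv` plus `thresholds.json`, `clusters.tsv`,
#' `crucial_subnetwork.sif` (induced subgraph on the crucial nodes),
#' `degree_distribution.tsv` and `degree_fit.json`, `enrichment.tsv` and
#' `term_edges.tsv` (when annotations are configured), and `manifest.json`.
#' Apart from the timestamp in the manifest, reruns on the same inputs are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  log_line <- function(...) message(sprintf(...))

  graph <- stage("read", read_input_graph(config))
  log_line("read: %d nodes, %d edges", igraph::vcount(graph),
           igraph::ecount(graph))

  summary <- stage("summarize", summarize_graph(graph))
  write_graph_summary(summary, out("summary.json"))

  empty <- igraph::vcount(graph) == 0
  if (empty) warning("input graph is empty; writing header-only tables")

  table <- stage("centrality", centrality_table(graph))
  write_tables(stats::setNames(table, c("Name", "D", "BC", "CC")),
               out("centrality.tsv"))
  log_line("centrality: %d records", nrow(table))

  selection <- NULL
  if (!empty) {
    selection <- stage("selection", select_crucial(table, config$selection))
  }
  sel_tab <- if (is.null(selection)) {
    data.frame(node = character(), degree = integer(),
               betweenness = numeric(), closeness = numeric(),
               hub = logical(), bottleneck = logical(),
               high_closeness = logical(), crucial = logical())
  } else selection_table(selection, table)
  write_tables(sel_tab, out("selection.tsv"))
  jsonlite::write_json(
    list(degree_threshold = if (is.null(selection)) NA else
           selection$degree_threshold,
         hub_sd_multiplier = config$selection$hub_sd_multiplier,
         top_fraction = config$selection$top_fraction,
         sd_mode = config$selection$sd_mode,
         n_hubs = length(selection$hubs),
         n_bottlenecks = length(selection$bottlenecks),
         n_high_closeness = length(selection$high_closeness),
         n_crucial = length(selection$crucial)),
    out("thresholds.json"), auto_unbox = TRUE, digits = NA)
  log_line("selection: %d hubs, %d crucial",
           length(selection$hubs), length(selection$crucial))

  clusters <- stage("clustering", find_clusters(graph, config$clusters))
  write_tables(as.data.frame(clusters), out("clusters.tsv"))
  log_line("clustering: %d significant cluster(s)", length(clusters))

  crucial <- if (is.null(selection)) character(0) else selection$crucial
  subnet <- stage("subnetwork", extract_subnetwork(graph, crucial))
  write_sif(subnet, out("crucial_subnetwork.sif"))

  hist <- stage("degree_fit", degree_histogram(graph))
  fit <- NULL
  if (sum(hist$k >= 1 & hist$count >= 1) >= 2) {
    fit <- stage("degree_fit", fit_power_law(hist))
    write_tables(degree_fit_table(hist, fit), out("degree_distribution.tsv"))
    jsonlite::write_json(unclass(fit), out("degree_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    log_line("degree fit: N(k) = %.4g k^%.4g", fit$a, fit$b)
  } else {
    write_tables(data.frame(k = hist$k, count = hist$count,
                            fitted = rep(NA_real_, nrow(hist))),
                 out("degree_distribution.tsv"))
  }

  enrichment <- NULL
  if (!is.null(config$annotations)) {
    ann <- stage("enrichment", read_annotations(
      config$annotations, config$term_names,
      universe = union(igraph::V(graph)$name,
                       utils::read.table(config$annotations, sep = "\t",
                                         stringsAsFactors = FALSE)[[2]])))
    query <- if (config$enrich_target == "crucial") crucial
             else if (length(clusters) > 0) clusters[[1]]$members
             else character(0)
    if (length(query) > 0) {
      enrichment <- stage("enrichment",
                          enrich(query, ann, config$correction,
                                 config$kappa_threshold))
      write_tables(enrichment, out("enrichment.tsv"))
      write_tables(kappa_edges(ann, enrichment$term, config$kappa_threshold),
                   out("term_edges.tsv"))
      log_line("enrichment: %d term(s) in %d group(s)", nrow(enrichment),
               if (nrow(enrichment)) max(enrichment$group) else 0)
    } else {
      warning("no enrichment query (no significant cluster / empty crucial set)")
      write_tables(data.frame(term = character(), name = character(),
                              k = integer(), K = integer(), n = integer(),
                              N = integer(), p_value = numeric(),
                              p_adjusted = numeric(), group = integer()),
                   out("enrichment.tsv"))
    }
  }

  manifest <- list(
    package = "ppinet",
    version = as.character(utils::packageVersion("ppinet")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = config_digest(config),
    counts = list(nodes = igraph::vcount(graph),
                  edges = igraph::ecount(graph),
                  hubs = length(selection$hubs),
                  crucial = length(crucial),
                  clusters = length(clusters))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)

  invisible(list(graph = graph, summary = summary, centrality = table,
                 selection = selection, clusters = clusters,
                 subnetwork = subnet, degree_fit = fit,
                 enrichment = enrichment))
}

#' @keywords internal
#' @noRd
config_digest <- function(config) {
  flat <- list(input = config$input, input_format = config$input_format,
               score_threshold = config$score_threshold,
               selection = unclass(config$selection),
               clusters = unclass(config$clusters),
               enrich_target = config$enrich_target,
               correction = config$correction,
               kappa_threshold = config$kappa_threshold)
  flat
}
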