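# Build orchestration: the staged construction flow.
#
# Stage order is fixed: load-ontologies -> rdfize -> owl-to-ice -> entity
# typing -> exact matches -> identifier sets -> BIO entities -> BIO rule
# batches. The graph lives in memory; each stage can checkpoint its delta as
# gzip-compressed N-Triples into a working directory so stages can be re-run
# and their output used on its own.

#' Load the build configuration
#'
#' @param path YAML config path; defaults to the configuration shipped with
#'   the package (sources, mapping specs, entity-type assertions, rule-batch
#'   order).
#' @return Parsed config list.
#' @export
kb_build_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "config", "build.yaml", package = "icekb")
  }
  yaml::read_yaml(path)
}

.stage_delta <- function(graph, before) {
  if (is.null(before)) return(data.table::copy(graph$dt))
  data.table::fsetdiff(graph$dt, before)
}

#' Run the full knowledge-base build
#'
#' Executes every stage in order over the source files in `source_dir`,
#' optionally checkpointing per-stage N-Triples, the exact-match edge table,
#' the identifier-set table, the build log and a stage report into `workdir`.
#'
#' @param source_dir Directory holding the source files named in the config
#'   (e.g. a fixture directory from [generate_sources()]).
#' @param workdir Optional working directory for checkpoints and logs.
#' @param config Build config from [kb_build_config()].
#' @param schemas,dialects Schema and dialect tables.
#' @param quiet Suppress progress messages.
#' @return List: `graph`, `report` (stage, new_triples, total), `edges`,
#'   `sets`, `rule_counts`, `reduction` (per-source field-value reduction
#'   stats), `parse_reports`.
#' @export
kb_build <- function(source_dir, workdir = NULL, config = kb_build_config(),
                     schemas = kb_schemas(), dialects = kb_dialects(),
                     quiet = TRUE) {
  graph <- kb_graph()
  report <- list()
  say <- function(...) if (!quiet) message(...)
  checkpoint <- local({
    n_stage <- 0L
    function(stage, before) {
      n_stage <<- n_stage + 1L
      delta <- .stage_delta(graph, before)
      report[[length(report) + 1L]] <<- data.table::data.table(
        stage = stage, new_triples = nrow(delta), total = kb_size(graph))
      if (!is.null(workdir)) {
        write_ntriples(delta, file.path(workdir,
                                        sprintf("%02d-%s.nt.gz", n_stage, stage)))
      }
      say("stage ", stage, ": +", nrow(delta), " triples (", kb_size(graph), " total)")
    }
  })
  if (!is.null(workdir)) dir.create(workdir, showWarnings = FALSE, recursive = TRUE)

  before <- NULL
  for (onto in config$ontologies) {
    load_ontology(file.path(source_dir, onto), graph)
  }
  checkpoint("ontology", before)

  before <- data.table::copy(graph$dt)
  reduction <- list()
  parse_reports <- list()
  for (src in config$sources) {
    sc <- schemas[[src$schema]]
    path <- file.path(source_dir, src$file)
    parsed <- if (identical(sc$format, "gaf")) read_gaf(path, sc)
              else read_delimited(path, sc)
    for (line in format_parse_report(parsed$report)) kb_log(graph, line)
    batch <- rdfize_table(parsed$rows, sc, dialects, graph)
    reduction[[src$schema]] <- triple_reduction_stats(batch, graph)
    parse_reports[[src$schema]] <- parsed$report
  }
  checkpoint("ice-records", before)

  before <- data.table::copy(graph$dt)
  generate_ontology_ice(graph, dialects,
                        spaces = config$ontology_ice_spaces %||% c("GO", "NCBITaxon"))
  checkpoint("owl-to-ice", before)

  before <- data.table::copy(graph$dt)
  type_map <- vapply(config$type_assertions, expand_curie, character(1))
  assert_entity_types(graph, type_map)
  expand_macro(graph)
  checkpoint("entity-types", before)

  before <- data.table::copy(graph$dt)
  edges <- extract_exact_matches(graph, config$mapping_specs, schemas)
  checkpoint("exact-matches", before)
  if (!is.null(workdir)) {
    utils::write.table(edges, file.path(workdir, "05-edges.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  before <- data.table::copy(graph$dt)
  sets <- make_identifier_sets(graph, edges)
  checkpoint("id-sets-and-entities", before)
  if (!is.null(workdir)) {
    utils::write.table(sets, file.path(workdir, "06-idsets.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  before <- data.table::copy(graph$dt)
  rule_counts <- list()
  for (rf in config$rule_batches) {
    res <- run_rule_batch(graph, rf)
    rule_counts[[rf]] <- res$counts
  }
  checkpoint("bio-rules", before)

  report <- data.table::rbindlist(report)
  if (!is.null(workdir)) {
    writeLines(graph$log, file.path(workdir, "build.log"))
    utils::write.table(report, file.path(workdir, "report.txt"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  list(graph = graph, report = report, edges = edges, sets = sets,
       rule_counts = data.table::rbindlist(rule_counts),
       reduction = reduction, parse_reports = parse_reports)
}

#' Recovered identifier partition of a built graph
#'
#' @param build Result of [kb_build()] (or a graph with `id_sets` cached).
#' @return List of character vectors (members per set), sorted canonically --
#'   directly comparable to a fixture manifest's `partition`.
#' @export
recovered_partition <- function(build) {
  sets <- if (inherits(build, "kb_graph")) build$id_sets else build$sets
  out <- lapply(split(sets$member, sets$set_uri), sort, method = "radix")
  names(out) <- NULL
  out[order(vapply(out, `[[`, character(1), 1L), method = "radix")]
}

#' The fixture-scale drug-retrieval demonstration query
#'
#' Retrieves drugs that interact (through the gene-or-gene-product-or-variant
#' aggregate classes) with genes whose proteins both participate in a process
#' under the given process class and localize to the given component --
#' posed purely in biomedical terms, with transitive subclass steps as `*`
#' property paths.
#'
#' @param graph A built [kb_graph()].
#' @param process Process class URI/CURIE (default: the
#'   oxidative-phosphorylation-like class).
#' @param component Component class URI/CURIE (default: the
#'   mitochondrion-like class).
#' @return data.table: drug (BIO class URI), ids (space-separated denoting
#'   identifier ICEs).
#' @export
demo_query <- function(graph, process = "obo:GO_0006119",
                       component = "obo:GO_0005739") {
  kbio <- kb_namespaces()[["kbio"]]
  body <- list(
    c("?proc", "rdfs:subClassOf*", process),
    c("?proc", "rdfs:subClassOf", "?pp"),
    c("?pp", "rdf:type", "owl:Restriction"),
    c("?pp", "owl:onProperty", "obo:RO_0000057"),
    c("?pp", "owl:someValuesFrom", "?protein"),
    c("?protein", "rdfs:subClassOf", "obo:PR_000000001"),
    c("?loc", "rdfs:subClassOf", "?pp"),
    c("?loc", "rdfs:subClassOf", "?lr"),
    c("?lr", "owl:onProperty", "obo:RO_0001025"),
    c("?lr", "owl:someValuesFrom", "?comp"),
    c("?comp", "rdfs:subClassOf*", component),
    c("?protein", "rdfs:subClassOf", "?agg"),
    c("?rg", "owl:someValuesFrom", "?agg"),
    c("?rg", "owl:onProperty", "obo:RO_0000057"),
    c("?i", "rdfs:subClassOf", "?rg"),
    c("?i", "rdfs:subClassOf*", "obo:MI_0000"),
    c("?i", "rdfs:subClassOf", "?rd"),
    c("?rd", "owl:onProperty", "obo:RO_0000057"),
    c("?rd", "owl:someValuesFrom", "?drug"),
    c("?drug", "rdfs:subClassOf", "obo:CHEBI_23888"))
  filters <- list(list(var = "?protein", prefix = paste0(kbio, "BIO_")),
                  list(var = "?agg", prefix = paste0(kbio, "GorGPorV_BIO_")),
                  list(var = "?drug", prefix = paste0(kbio, "BIO_")),
                  list(var = "?proc", prefix = paste0(kbio, "GOA_")),
                  list(var = "?loc", prefix = paste0(kbio, "LOC_")))
  hits <- match_body(body, graph, filters)
  if (nrow(hits) == 0L) {
    return(data.table::data.table(drug = character(), ids = character()))
  }
  drugs <- sort(unique(hits$drug), method = "radix")
  ids <- vapply(drugs, function(d) {
    paste(sort(trace_concept(d, graph)$denoting_ids), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
  data.table::data.table(drug = drugs, ids = ids)
}

#' Require checkpoint files before a single-stage command
#'
#' @param workdir Working directory.
#' @param patterns Glob patterns of required checkpoint files.
#' @param stage Name of the stage being attempted (for the error message).
#' @return Invisibly `TRUE`; raises `StageOrderViolation` if any is missing.
#' @export
kb_stage_require <- function(workdir, patterns, stage) {
  for (p in patterns) {
    if (length(Sys.glob(file.path(workdir, p))) == 0L) {
      stop(.condition("StageOrderViolation",
                      paste0("stage '", stage, "' needs ", p,
                             " in ", workdir, "; run the earlier stages first")))
    }
  }
  invisible(TRUE)
}

#' Load a graph from the checkpoints in a working directory
#'
#' @param workdir Working directory with `NN-stage.nt.gz` checkpoints.
#' @return A [kb_graph()] holding the union of all checkpointed triples.
#' @export
kb_load_workdir <- function(workdir) {
  graph <- kb_graph()
  for (f in sort(Sys.glob(file.path(workdir, "*.nt.gz")))) {
    kb_add(graph, read_ntriples(f))
  }
  edges_f <- file.path(workdir, "05-edges.tsv")
  if (file.exists(edges_f)) {
    graph$xmatch_edges <- data.table::fread(edges_f, sep = "\t",
                                            colClasses = "character")
  }
  sets_f <- file.path(workdir, "06-idsets.tsv")
  if (file.exists(sets_f)) {
    graph$id_sets <- data.table::fread(sets_f, sep = "\t",
                                       colClasses = "character")
  }
  graph
}
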