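# Readers for the formats the pipeline touches: schema-driven delimited
# files, GAF 2.x annotation files, and ontology files in the Turtle subset.
# Every parse produces a ParseReport whose arithmetic always balances:
# rows read = rows emitted + rows quarantined.

# field splitter that keeps trailing empty fields
.split_fields <- function(line, delim) {
  cells <- strsplit(paste0(line, delim, "\x01"), delim, fixed = TRUE)[[1]]
  cells[-length(cells)]
}

#' Load the schema templates
#'
#' @param path YAML schema config; defaults to the table shipped with the
#'   package.
#' @return Named list of `kb_schema` objects with precomputed schema, field,
#'   record-class and field-value-class URIs.
#' @export
kb_schemas <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "config", "schemas.yaml", package = "icekb")
  }
  cfg <- yaml::read_yaml(path)
  kiao <- kb_namespaces()[["kiao"]]
  out <- list()
  for (nm in names(cfg$schemas)) {
    sc <- cfg$schemas[[nm]]
    sc$name <- nm
    sc$uri <- paste0(kiao, "schema/", nm)
    sc$record_class <- paste0(sc$uri, "/Record")
    sc$fv_class <- paste0(sc$uri, "/FieldValue")
    fields <- list()
    for (f in sc$fields) {
      f$uri <- paste0(sc$uri, "/", f$name)
      fields[[f$name]] <- f
    }
    stopifnot(!anyDuplicated(names(fields)))
    sc$fields <- fields
    class(sc) <- "kb_schema"
    out[[nm]] <- sc
  }
  out
}

#' Field ICE URI of a schema field
#' @param schema A `kb_schema`.
#' @param field Field name.
#' @return Field ICE URI.
#' @export
schema_field_uri <- function(schema, field) {
  f <- schema$fields[[field]]
  if (is.null(f)) stop("schema '", schema$name, "' has no field '", field, "'")
  f$uri
}

.new_report <- function(file) {
  list(file = file, rows_read = 0L, rows_quarantined = 0L, warnings = character())
}

#' Read a schema-described delimited file
#'
#' Header-driven: the header must contain every schema field (otherwise a
#' `MissingColumns` error signals source format drift); unknown extra columns
#' are parsed and logged by name; rows with the wrong column count are
#' quarantined with a warning, never silently dropped.
#'
#' @param path File path.
#' @param schema A `kb_schema` from [kb_schemas()].
#' @return List with `rows` (list of named character vectors, schema fields
#'   only) and `report` (a ParseReport: file, rows_read, rows_quarantined,
#'   warnings).
#' @export
read_delimited <- function(path, schema) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  report <- .new_report(path)
  if (length(lines) == 0L) return(list(rows = list(), report = report))
  delim <- schema$delimiter
  header <- .split_fields(lines[[1]], delim)
  wanted <- names(schema$fields)
  missing <- setdiff(wanted, header)
  if (length(missing) > 0L) {
    stop(.condition("MissingColumns",
                    paste0(path, ": mandatory column(s) absent: ",
                           paste(missing, collapse = ", "))))
  }
  extra <- setdiff(header, wanted)
  if (length(extra) > 0L) {
    report$warnings <- c(report$warnings,
                         paste0("unknown column(s) ignored: ", paste(extra, collapse = ", ")))
  }
  body <- lines[-1]
  report$rows_read <- length(body)
  rows <- vector("list", length(body))
  keep <- logical(length(body))
  for (i in seq_along(body)) {
    cells <- .split_fields(body[[i]], delim)
    if (length(cells) != length(header)) {
      report$rows_quarantined <- report$rows_quarantined + 1L
      report$warnings <- c(report$warnings,
                           paste0("row ", i, " quarantined: expected ", length(header),
                                  " columns, got ", length(cells)))
      next
    }
    names(cells) <- header
    rows[[i]] <- cells[wanted]
    keep[i] <- TRUE
  }
  list(rows = rows[keep], report = report)
}

#' Read a GAF 2.x gene-association file
#'
#' Tab-delimited, 17 columns, `!`-prefixed comment lines skipped. Columns 1-2
#' (DB, DB object ID), 5 (GO ID), 7 (evidence), 9 (aspect) and 13 (taxon) are
#' consumed; rows with any other column count are quarantined with a warning.
#' Object and GO identifiers are returned raw here and canonicalized during
#' RDFization like every other identifier field.
#'
#' @param path GAF file path.
#' @param schema The `goa` schema (supplies field names), see [kb_schemas()].
#' @return List with `rows` and `report` as in [read_delimited()].
#' @export
read_gaf <- function(path, schema = kb_schemas()[["goa"]]) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  report <- .new_report(path)
  report$rows_read <- length(lines)
  rows <- list()
  for (i in seq_along(lines)) {
    cells <- .split_fields(lines[[i]], "\t")
    if (length(cells) != 17L) {
      report$rows_quarantined <- report$rows_quarantined + 1L
      report$warnings <- c(report$warnings,
                           paste0("annotation line ", i, " quarantined: ",
                                  length(cells), " columns (expected 17)"))
      next
    }
    rows[[length(rows) + 1L]] <- c(
      row_id = as.character(i),
      db = cells[[1]], object_id = cells[[2]], go_id = cells[[5]],
      evidence = cells[[7]], aspect = cells[[9]], taxon_id = cells[[13]])
  }
  list(rows = rows, report = report)
}

#' Load an ontology file into a triple table
#'
#' Ontologies are the vocabulary backbone: a parse failure aborts the build.
#' A subclass cycle is loaded (validation is not this layer's job) but logged
#' as a warning.
#'
#' @param path Ontology path (Turtle subset, or N-Triples when the path ends
#'   in `.nt`/`.nt.gz`).
#' @param graph Optional [kb_graph()]; when given, triples are added and the
#'   cycle warning goes to its build log.
#' @return data.table of ontology triples.
#' @export
load_ontology <- function(path, graph = NULL) {
  trip <- if (grepl("\\.nt(\\.gz)?$", path)) read_ntriples(path) else read_turtle(path)
  sub <- trip[trip$p == expand_curie("rdfs:subClassOf") & !kb_is_literal(trip$o), ]
  if (nrow(sub) > 0L && .has_cycle(sub$s, sub$o)) {
    msg <- paste0("ontology ", path, " contains an rdfs:subClassOf cycle")
    if (!is.null(graph)) kb_log(graph, "WARN ", msg) else warning(msg)
  }
  if (!is.null(graph)) kb_add(graph, trip)
  trip
}

# simple DFS cycle detection on an edge list
.has_cycle <- function(from, to) {
  nodes <- unique(c(from, to))
  adj <- split(to, factor(from, levels = nodes))
  state <- stats::setNames(integer(length(nodes)), nodes) # 0 new, 1 open, 2 done
  for (start in nodes) {
    if (state[[start]] != 0L) next
    stack <- list(list(node = start, i = 0L))
    state[[start]] <- 1L
    while (length(stack) > 0L) {
      top <- stack[[length(stack)]]
      nbrs <- adj[[top$node]]
      if (is.null(nbrs) || top$i >= length(nbrs)) {
        state[[top$node]] <- 2L
        stack[[length(stack)]] <- NULL
        next
      }
      stack[[length(stack)]]$i <- top$i + 1L
      nb <- nbrs[[top$i + 1L]]
      if (state[[nb]] == 1L) return(TRUE)
      if (state[[nb]] == 0L) {
        state[[nb]] <- 1L
        stack[[length(stack) + 1L]] <- list(node = nb, i = 0L)
      }
    }
  }
  FALSE
}

#' Format a ParseReport as build-log lines
#' @param report A ParseReport from a reader.
#' @return Character vector of log lines.
#' @export
format_parse_report <- function(report) {
  c(paste0("parsed ", report$file, ": ", report$rows_read, " rows, ",
           report$rows_quarantined, " quarantined"),
    paste0("WARN ", report$warnings))
}
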