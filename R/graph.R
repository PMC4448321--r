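# In-memory triple store.
#
# Triples are rows of a data.table with character columns (s, p, o). URIs are
# stored as bare strings; literal objects are stored in N-Triples quoted form
# (leading '"') so URIs and literals can never be confused and set semantics
# reduce to string equality. The store is an environment so stages mutate one
# shared graph, mirroring an incrementally loaded triplestore; each stage can
# be checkpointed to gzip-compressed N-Triples.

#' Encode a literal value for storage
#'
#' @param x Character vector of literal values.
#' @return N-Triples-quoted strings (`"..."` with `\` and `"` escaped).
#' @export
kb_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  paste0("\"", x, "\"")
}

#' Test whether stored terms are literals
#' @param x Character vector of stored terms.
#' @return Logical vector.
#' @export
kb_is_literal <- function(x) startsWith(x, "\"")

#' Decode a stored literal back to its value
#' @param x Stored literal terms.
#' @return Unquoted literal values.
#' @export
kb_literal_value <- function(x) {
  x <- sub("^\"", "", sub("\"$", "", x))
  x <- gsub("\\\"", "\"", x, fixed = TRUE)
  gsub("\\\\", "\\", x, fixed = TRUE)
}

#' Build a triple table
#'
#' Convenience constructor: CURIEs in subject/predicate/object position are
#' expanded against the build namespace table; literals must already be in
#' [kb_literal()] form.
#'
#' @param s,p,o Equal-length character vectors.
#' @return data.table with columns s, p, o.
#' @export
kb_triples <- function(s, p, o) {
  data.table::data.table(s = expand_curie(s), p = expand_curie(p),
                         o = expand_curie(o))
}

#' Create an empty knowledge-base graph
#'
#' @return An object of class `kb_graph`: an environment holding the triple
#'   table, the derivation index (see [kb_derivations()]) and the build log.
#' @export
kb_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$dt <- data.table::data.table(s = character(), p = character(), o = character())
  data.table::setkeyv(g$dt, c("s", "p", "o"))
  g$deriv <- data.table::data.table(s = character(), p = character(), o = character(),
                                    rule = character(), binding = character(),
                                    records = character())
  g$log <- character()
  class(g) <- "kb_graph"
  g
}

#' @export
print.kb_graph <- function(x, ...) {
  cat("<kb_graph> ", nrow(x$dt), " triples, ",
      nrow(unique(x$deriv[, c("s", "p", "o")])), " rule-derived\n", sep = "")
  invisible(x)
}

#' Number of triples in a graph
#' @param graph A [kb_graph()].
#' @return Integer triple count.
#' @export
kb_size <- function(graph) nrow(graph$dt)

#' Append a line to the build log
#' @param graph A [kb_graph()].
#' @param ... Parts pasted into one log line.
#' @return The graph, invisibly.
#' @export
kb_log <- function(graph, ...) {
  graph$log <- c(graph$log, paste0(...))
  invisible(graph)
}

#' Add triples to a graph
#'
#' Duplicate triples (already present, or repeated within `triples`) are
#' dropped; the graph is strictly monotone -- triples are only ever added.
#'
#' @param graph A [kb_graph()].
#' @param triples data.table/data.frame with columns s, p, o.
#' @return Number of genuinely new triples added (drives fixpoint detection).
#' @export
kb_add <- function(graph, triples) {
  if (is.null(triples) || nrow(triples) == 0L) return(0L)
  new <- unique(data.table::as.data.table(triples)[, c("s", "p", "o")])
  if (nrow(graph$dt) > 0L) {
    idx <- graph$dt[new, on = c("s", "p", "o"), which = TRUE]
    new <- new[is.na(idx)]
  }
  if (nrow(new) == 0L) return(0L)
  graph$dt <- rbind(graph$dt, new)
  data.table::setkeyv(graph$dt, c("s", "p", "o"))
  nrow(new)
}

#' Test whether triples are present
#'
#' @param graph A [kb_graph()].
#' @param triples data.table with columns s, p, o.
#' @return Logical vector, one per row of `triples`.
#' @export
kb_has <- function(graph, triples) {
  triples <- data.table::as.data.table(triples)
  !is.na(graph$dt[triples, on = c("s", "p", "o"), which = TRUE])
}

#' Retrieve triples matching a simple pattern
#'
#' `NA` in a position is a wildcard. CURIEs are expanded.
#'
#' @param graph A [kb_graph()].
#' @param s,p,o Term or `NA`.
#' @return data.table of matching triples.
#' @export
kb_find <- function(graph, s = NA, p = NA, o = NA) {
  dt <- graph$dt
  keep <- rep(TRUE, nrow(dt))
  if (!is.na(s)) keep <- keep & (dt[["s"]] == expand_curie(s))
  if (!is.na(p)) keep <- keep & (dt[["p"]] == expand_curie(p))
  if (!is.na(o)) keep <- keep & (dt[["o"]] == expand_curie(o))
  dt[which(keep)]
}

#' The derivation index
#'
#' One row per (triple, rule, binding) derivation recorded while rules ran;
#' a triple produced by two rules or two bindings carries two rows.
#'
#' @param graph A [kb_graph()].
#' @return data.table with columns s, p, o, rule, binding (JSON), records.
#' @export
kb_derivations <- function(graph) data.table::copy(graph$deriv)

# record derivations (internal): deriv_dt has s,p,o,rule,binding,records
kb_record_derivations <- function(graph, deriv_dt) {
  if (is.null(deriv_dt) || nrow(deriv_dt) == 0L) return(invisible(graph))
  graph$deriv <- unique(rbind(graph$deriv, deriv_dt))
  invisible(graph)
}

# ---- N-Triples I/O ---------------------------------------------------------

.nt_term <- function(x) {
  ifelse(kb_is_literal(x), x, paste0("<", x, ">"))
}

#' Write a graph (or triple table) to N-Triples
#'
#' Lines are sorted (byte order) so identical graphs serialize to identical
#' bytes; `.gz` paths are compressed transparently.
#'
#' @param triples A [kb_graph()] or a data.table with columns s, p, o.
#' @param path Output path; compressed when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_ntriples <- function(triples, path) {
  if (inherits(triples, "kb_graph")) triples <- triples$dt
  lines <- paste(.nt_term(triples$s), .nt_term(triples$p), .nt_term(triples$o), ".")
  lines <- sort(lines, method = "radix")
  con <- if (endsWith(path, ".gz")) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read an N-Triples file into a triple table
#'
#' @param path N-Triples path (optionally gzipped).
#' @return data.table with columns s, p, o.
#' @export
read_ntriples <- function(path) {
  con <- if (endsWith(path, ".gz")) gzfile(path, "rb") else file(path, "rb")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parse_one <- function(line) {
    line <- sub("\\s*\\.\\s*$", "", line)
    terms <- character(3)
    for (i in 1:3) {
      line <- sub("^\\s+", "", line)
      if (startsWith(line, "<")) {
        end <- regexpr(">", line, fixed = TRUE)
        if (end < 0) stop("malformed N-Triples term: ", line)
        terms[i] <- substr(line, 2L, end - 1L)
        line <- substring(line, end + 1L)
      } else if (startsWith(line, "\"")) {
        # find closing unescaped quote
        chars <- strsplit(line, "", fixed = TRUE)[[1]]
        j <- 2L
        while (j <= length(chars)) {
          if (chars[j] == "\\") { j <- j + 2L; next }
          if (chars[j] == "\"") break
          j <- j + 1L
        }
        if (j > length(chars)) stop("unterminated literal: ", line)
        terms[i] <- substr(line, 1L, j)
        line <- substring(line, j + 1L)
        # drop any datatype/lang tag up to next whitespace
        line <- sub("^(\\^\\^<[^>]*>|@[A-Za-z0-9-]+)", "", line)
      } else stop("malformed N-Triples line at: ", line)
    }
    terms
  }
  mat <- vapply(lines, parse_one, character(3), USE.NAMES = FALSE)
  if (length(mat) == 0L) {
    return(data.table::data.table(s = character(), p = character(), o = character()))
  }
  data.table::data.table(s = mat[1, ], p = mat[2, ], o = mat[3, ])
}

# ---- Turtle subset ---------------------------------------------------------
# Ontology fixtures are written in a plain Turtle subset: @prefix headers and
# one "S P O ." statement per line ("a" allowed as rdf:type). The reader
# accepts exactly that subset plus comments; it exists because no RDF parser
# ships with the R stack this package targets.

#' Write a triple table as simple Turtle
#'
#' @param triples data.table with columns s, p, o.
#' @param path Output path.
#' @param prefixes Named character vector of namespace prefixes to declare.
#' @return `path`, invisibly.
#' @export
write_turtle <- function(triples, path, prefixes = kb_namespaces()) {
  header <- sprintf("@prefix %s: <%s> .", names(prefixes), unname(prefixes))
  term <- function(x) {
    cx <- compact_uri(x)
    ifelse(kb_is_literal(x), x, ifelse(cx == x, paste0("<", x, ">"), cx))
  }
  body <- paste(term(triples$s),
                ifelse(triples$p == expand_curie("rdf:type"), "a", term(triples$p)),
                term(triples$o), ".")
  writeLines(c(header, "", sort(body, method = "radix")), path, useBytes = TRUE)
  invisible(path)
}

#' Read the simple Turtle subset
#'
#' Supports `@prefix` declarations, comments, and one `S P O .` statement per
#' line with prefixed names, `<full URIs>`, `a`, and plain `"literals"`.
#'
#' @param path Turtle file path.
#' @return data.table with columns s, p, o (URIs expanded).
#' @export
read_turtle <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  pre <- grepl("^@prefix", lines)
  prefixes <- character()
  for (l in lines[pre]) {
    m <- regmatches(l, regexec("^@prefix\\s+([A-Za-z][A-Za-z0-9]*):\\s+<([^>]*)>\\s*\\.\\s*$", l))[[1]]
    if (length(m) != 3L) stop("malformed @prefix line: ", l)
    prefixes[m[2]] <- m[3]
  }
  stmts <- lines[!pre]
  if (length(stmts) == 0L) stop("ontology file contains no statements: ", path)
  expand <- function(t) {
    if (t == "a") return(expand_curie("rdf:type"))
    if (startsWith(t, "<")) return(sub(">$", "", sub("^<", "", t)))
    if (startsWith(t, "\"")) return(t)
    m <- regmatches(t, regexec("^([A-Za-z][A-Za-z0-9]*):(.+)$", t))[[1]]
    if (length(m) == 3L && m[2] %in% names(prefixes)) return(paste0(prefixes[[m[2]]], m[3]))
    stop("unresolvable term in Turtle subset: ", t)
  }
  parse_stmt <- function(l) {
    l <- sub("\\s*\\.\\s*$", "", l)
    # literals in this subset contain no unescaped whitespace-quote ambiguity:
    # split into three tokens, quoted literal only in object position
    m <- regmatches(l, regexec("^(\\S+)\\s+(\\S+)\\s+(.+)$", l))[[1]]
    if (length(m) != 4L) stop("malformed Turtle statement: ", l)
    c(expand(m[2]), expand(m[3]), expand(trimws(m[4])))
  }
  mat <- vapply(stmts, parse_stmt, character(3), USE.NAMES = FALSE)
  data.table::data.table(s = mat[1, ], p = mat[2, ], o = mat[3, ])
}
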