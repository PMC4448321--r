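# Identifier identity resolution across sources.
#
# Bootstrap entity typing (kiao:denotesSubClassOf) breaks the circularity of
# needing to know what an identifier will denote before its concept exists;
# type-guarded rules then extract skos:exactMatch links only between
# identifiers denoting the same kind of thing; union-find closes the links
# into disjoint identifier sets; each set is materialized (kro:hasMember) and
# given one BIO concept that every member identifier iao:denotes -- the only
# triples crossing the ICE/BIO divide at this stage.

#' Assert bootstrap entity types for identifier spaces
#'
#' Every identifier ICE in the graph whose space appears in `type_map` gets a
#' `kiao:denotesSubClassOf` assertion to the mapped ontology class (e.g. all
#' gene-space identifiers to the gene sequence class). Identifiers from spaces
#' without a type assertion are left ICE-only and logged.
#'
#' @param graph A [kb_graph()].
#' @param type_map Named character vector: space label -> class CURIE/URI.
#' @return Number of new triples.
#' @export
assert_entity_types <- function(graph, type_map) {
  vals <- unique(kb_find(graph, p = "kiao:has_field_value")$o)
  ids <- vals[!kb_is_literal(vals) & is_ice_uri(vals) & endsWith(vals, "_ICE")]
  spaces <- id_space(ids)
  typed <- spaces %in% names(type_map)
  untyped_spaces <- unique(spaces[!typed & !is.na(spaces)])
  if (length(untyped_spaces) > 0L) {
    kb_log(graph, "identifier spaces without entity-type assertion (left ICE-only): ",
           paste(untyped_spaces, collapse = ", "))
  }
  if (!any(typed)) return(0L)
  kb_add(graph, kb_triples(ids[typed], "kiao:denotesSubClassOf",
                           unname(type_map[spaces[typed]])))
}

# class-compatibility under the loaded subclass hierarchy:
# identical, or one subsumes the other
.subclass_closure_of <- function(graph, class_uri) {
  edges <- kb_find(graph, p = "rdfs:subClassOf")
  up <- .reachable(edges$s, edges$o, class_uri)[[class_uri]]
  up
}

compatible_types <- function(graph, a, b) {
  if (a == b) return(TRUE)
  b %in% .subclass_closure_of(graph, a) || a %in% .subclass_closure_of(graph, b)
}

#' Extract type-guarded exact-match edges from mapping records
#'
#' For each mapping spec (schema + left/right field), finds record-supplied
#' identifier pairs and emits a skos:exactMatch link only when both
#' identifiers carry compatible kiao:denotesSubClassOf types (identical or
#' one subsuming the other). Cross-type candidates (a gene mapped to a
#' protein or drug in a dbXref field) and untyped candidates are filtered --
#' filtering is the success path -- with filtered counts logged.
#'
#' @param graph A [kb_graph()] holding RDFized records and type assertions.
#' @param mapping_specs List of `{schema, left, right}` (field names).
#' @param schemas Schema table from [kb_schemas()].
#' @return data.table of edges: left, right, record (provenance record URI),
#'   schema. Also asserts the skos:exactMatch triples into the graph and
#'   caches the edges on the graph for QC.
#' @export
extract_exact_matches <- function(graph, mapping_specs, schemas = kb_schemas()) {
  all_edges <- list()
  types <- kb_find(graph, p = "kiao:denotesSubClassOf")
  type_of <- stats::setNames(types$o, types$s)
  # precompute pairwise class compatibility over the few guard classes
  classes <- unique(types$o)
  compat <- outer(classes, classes,
                  Vectorize(function(a, b) compatible_types(graph, a, b)))
  dimnames(compat) <- list(classes, classes)
  for (spec in mapping_specs) {
    sc <- schemas[[spec$schema]]
    body <- list(
      c("?r", "kiao:has_template", sc$uri),
      c("?r", "obo:has_part", "?lfv"),
      c("?lfv", "kiao:has_template", schema_field_uri(sc, spec$left)),
      c("?lfv", "kiao:has_field_value", "?left"),
      c("?r", "obo:has_part", "?rfv"),
      c("?rfv", "kiao:has_template", schema_field_uri(sc, spec$right)),
      c("?rfv", "kiao:has_field_value", "?right"))
    cand <- match_body(body, graph)
    if (nrow(cand) == 0L) next
    cand <- cand[cand$left != cand$right]
    lt <- type_of[cand$left]
    rt <- type_of[cand$right]
    ok <- !is.na(lt) & !is.na(rt) &
      compat[cbind(match(lt, classes), match(rt, classes))]
    kb_log(graph, "exact-match extraction over ", spec$schema, " (",
           spec$left, " ~ ", spec$right, "): ", sum(ok), " links, ",
           sum(!ok), " cross-type/untyped candidates filtered")
    if (!any(ok)) next
    edges <- data.table::data.table(left = cand$left[ok], right = cand$right[ok],
                                    record = cand$r[ok], schema = spec$schema)
    trip <- kb_triples(edges$left, "skos:exactMatch", edges$right)
    kb_add(graph, trip)
    kb_record_derivations(graph, data.table::data.table(
      s = trip$s, p = trip$p, o = trip$o,
      rule = paste0("exact-match:", spec$schema),
      binding = sprintf('{"r":"%s","left":"%s","right":"%s"}',
                        edges$record, edges$left, edges$right),
      records = edges$record))
    all_edges[[length(all_edges) + 1L]] <- edges
  }
  edges <- if (length(all_edges) > 0L) unique(data.table::rbindlist(all_edges)) else
    data.table::data.table(left = character(), right = character(),
                           record = character(), schema = character())
  graph$xmatch_edges <- edges
  edges
}

#' Union-find closure of exact-match edges
#'
#' Computes the transitive closure of the (undirected) exact-match links with
#' the union-find algorithm (union by size, path halving), partitioning the
#' universe of typed identifiers into disjoint sets; identifiers with no edges
#' form singleton sets. Output is deterministic: members sorted within sets,
#' sets sorted by first member.
#'
#' @param edges data.table/data.frame with columns `left`, `right` (or a
#'   2-column table of pairs).
#' @param universe Character vector of all identifiers to partition; edge
#'   endpoints must be contained in it.
#' @return List of character vectors (the disjoint identifier sets).
#' @export
union_find_closure <- function(edges, universe) {
  universe <- sort(unique(universe), method = "radix")
  n <- length(universe)
  if (n == 0L) return(list())
  idx <- stats::setNames(seq_len(n), universe)
  parent <- seq_len(n)
  size <- rep(1L, n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]] # path halving
      i <- parent[i]
    }
    i
  }
  if (!is.null(edges) && nrow(edges) > 0L) {
    l <- edges[[1]]; r <- edges[[2]]
    if (!all(c(l, r) %in% universe)) stop("edge endpoint outside the universe")
    for (k in seq_along(l)) {
      a <- find(idx[[l[k]]]); b <- find(idx[[r[k]]])
      if (a == b) next
      if (size[a] < size[b]) { tmp <- a; a <- b; b <- tmp }
      parent[b] <- a
      size[a] <- size[a] + size[b]
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sets <- split(universe, roots)
  sets <- lapply(sets, sort, method = "radix")
  names(sets) <- NULL
  sets[order(vapply(sets, `[[`, character(1), 1L), method = "radix")]
}

#' Materialize an identifier set as triples
#'
#' Emits exactly one kro:hasMember triple per member and nothing else; the
#' set's class membership is carried by its URI namespace (a convention that
#' keeps the per-set triple count equal to its member count).
#'
#' @param members Character vector of canonical identifier ICE URIs.
#' @return List: `uri` (permutation-invariant set URI), `triples`.
#' @export
materialize_id_set <- function(members) {
  uri <- mint_set_uri(members)
  list(uri = uri, triples = kb_triples(rep(uri, length(members)),
                                       "kro:hasMember", members))
}

#' Create the BIO concept for an identifier set
#'
#' Mints one BIO class per set (a pure function of the set URI), asserts it
#' rdfs:subClassOf the members' shared ontology type (the most specific of
#' the members' bootstrap guard classes), and asserts iao:denotes from every
#' member identifier ICE to the class. Members whose guard classes are
#' incomparable raise `MixedTypeSet` -- that signals an upstream filtering
#' bug, never a modeling choice.
#'
#' @param set_uri Set URI from [materialize_id_set()].
#' @param members The set's member identifier URIs.
#' @param graph A [kb_graph()] (supplies guard types and the subclass
#'   hierarchy).
#' @return List: `uri` (the BIO class), `triples`.
#' @export
create_bio_entity <- function(set_uri, members, graph) {
  types <- kb_find(graph, p = "kiao:denotesSubClassOf")
  guards <- unique(types$o[types$s %in% members])
  if (length(guards) == 0L) stop("no entity-type assertion for set ", set_uri)
  shared <- guards[[1]]
  for (g in guards[-1]) {
    if (g == shared) next
    # closure(x) walks upward, so "shared is an ancestor of g" means g is the
    # more specific guard
    if (shared %in% .subclass_closure_of(graph, g)) { shared <- g; next }
    if (g %in% .subclass_closure_of(graph, shared)) next
    stop(.condition("MixedTypeSet",
                    paste0("set ", set_uri, " mixes incomparable denoted types: ",
                           paste(guards, collapse = ", "))))
  }
  bio <- mint_bio_uri("set-entity", set_uri)
  list(uri = bio,
       triples = rbind(kb_triples(bio, "rdfs:subClassOf", shared),
                       kb_triples(members, "iao:denotes", rep(bio, length(members)))))
}

#' Resolve identifier identity over the whole graph
#'
#' Runs the set stage end-to-end: collects the universe of typed identifiers,
#' closes the exact-match edges with [union_find_closure()], materializes
#' every set and creates its BIO entity (singletons included, so every typed
#' identifier yields a denoted concept for downstream rules).
#'
#' @param graph A [kb_graph()].
#' @param edges Exact-match edges from [extract_exact_matches()].
#' @return data.table: set_uri, bio_uri, member (one row per member). Also
#'   cached on the graph as `graph$id_sets`.
#' @export
make_identifier_sets <- function(graph, edges) {
  types <- kb_find(graph, p = "kiao:denotesSubClassOf")
  universe <- unique(types$s)
  sets <- union_find_closure(edges, universe)
  rows <- list()
  for (members in sets) {
    m <- materialize_id_set(members)
    b <- create_bio_entity(m$uri, members, graph)
    trip <- rbind(m$triples, b$triples)
    kb_add(graph, trip)
    kb_record_derivations(graph, data.table::data.table(
      s = trip$s, p = trip$p, o = trip$o, rule = "id-set",
      binding = sprintf('{"set":"%s"}', m$uri), records = ""))
    rows[[length(rows) + 1L]] <- data.table::data.table(
      set_uri = m$uri, bio_uri = b$uri, member = members)
  }
  out <- data.table::rbindlist(rows)
  kb_log(graph, "identifier sets: ", length(sets), " sets over ",
         length(universe), " typed identifiers")
  graph$id_sets <- out
  out
}
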