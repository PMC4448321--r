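# Namespace table and CURIE handling.
#
# The graph keeps two strictly separated instance namespaces: kiao (ICE side:
# records, field values, identifier ICEs, identifier sets) and kbio (BIO side:
# generated biomedical concept classes). kro holds relations coined here;
# iao/obo/skos/rdf/rdfs/owl are the community vocabularies.

.ns_table <- c(
  kiao = "http://icekb.org/kiao/",
  kbio = "http://icekb.org/kbio/",
  kro  = "http://icekb.org/kro/",
  iao  = "http://purl.obolibrary.org/obo/iao/",
  obo  = "http://purl.obolibrary.org/obo/",
  skos = "http://www.w3.org/2004/02/skos/core#",
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl  = "http://www.w3.org/2002/07/owl#"
)

#' Namespace table
#'
#' Returns the fixed prefix-to-base table used for every URI in a build.
#' Prefixes are unique and each base is an absolute URI ending in `/` or `#`;
#' the table is immutable during a build so that minted URIs are stable.
#'
#' @return Named character vector mapping prefix to base URI.
#' @export
#' @examples
#' kb_namespaces()[["kiao"]]
kb_namespaces <- function() .ns_table

#' Expand a CURIE to a full URI
#'
#' Terms already in full-URI form (`<...>` or starting with a known base or
#' `http`) and literal terms (leading `"`) pass through unchanged, minus any
#' angle brackets.
#'
#' @param x Character vector of CURIEs, URIs, or literals.
#' @return Character vector of full URIs / literals.
#' @export
#' @examples
#' expand_curie("obo:GO_0006119")
expand_curie <- function(x) {
  out <- x
  angled <- startsWith(out, "<") & endsWith(out, ">")
  out[angled] <- substr(out[angled], 2L, nchar(out[angled]) - 1L)
  m <- regexpr("^([A-Za-z][A-Za-z0-9]*):(.*)$", out)
  for (i in seq_along(out)) {
    if (angled[i] || startsWith(out[i], "\"") || startsWith(out[i], "http")) next
    hit <- regmatches(out[i], regexec("^([A-Za-z][A-Za-z0-9]*):(.+)$", out[i]))[[1]]
    if (length(hit) == 3L && hit[2] %in% names(.ns_table)) {
      out[i] <- paste0(.ns_table[[hit[2]]], hit[3])
    }
  }
  out
}

#' Compact a full URI to a CURIE where a namespace matches
#'
#' @param x Character vector of full URIs.
#' @return Character vector with known bases replaced by `prefix:`.
#' @export
compact_uri <- function(x) {
  # longest base first so obo/iao nesting cannot mis-compact
  ord <- order(-nchar(.ns_table))
  for (i in ord) {
    base <- .ns_table[[i]]
    hit <- startsWith(x, base)
    x[hit] <- paste0(names(.ns_table)[i], ":", substring(x[hit], nchar(base) + 1L))
  }
  x
}

# Partition tests. Ontology-imported classes (obo:) sit on the BIO side of the
# ICE/BIO demarcation; everything minted under kiao: is ICE.
is_ice_uri <- function(x) startsWith(x, .ns_table[["kiao"]])
is_bio_uri <- function(x) {
  startsWith(x, .ns_table[["kbio"]]) |
    (startsWith(x, .ns_table[["obo"]]) & !startsWith(x, .ns_table[["iao"]]))
}
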