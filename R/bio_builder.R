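# BIO-side builders: thin wrappers that load the shipped declarative rule
# batches and run them to fixpoint. The science lives in inst/rules/*.yaml;
# these functions only orchestrate and add the checks a batch cannot express.

.rule_file <- function(name) {
  path <- system.file("rules", name, package = "icekb")
  if (!nzchar(path)) stop("rule file not found: ", name)
  path
}

#' Run one shipped rule batch to fixpoint
#'
#' @param graph A [kb_graph()].
#' @param file Rule file name under the package's `rules/` directory, or a
#'   full path to a user rule file.
#' @return Emission counts, see [run_batch_to_fixpoint()].
#' @export
run_rule_batch <- function(graph, file) {
  path <- if (file.exists(file)) file else .rule_file(file)
  run_batch_to_fixpoint(parse_rule_file(path), graph)
}

#' Build sequence-abstraction aggregates and gene-product links
#'
#' Per gene class: one gene-or-gene-product and one
#' gene-or-gene-product-or-variant aggregate (parallel-superclass encoding),
#' subclass links from the gene and each of its products into the aggregates,
#' and a kro:has_indirect_template link from protein to coding gene. Proteins
#' with no known coding gene are still represented; an OrphanProtein warning
#' is logged for each.
#'
#' @param graph A [kb_graph()].
#' @return Emission counts.
#' @export
build_abstractions <- function(graph) {
  res <- run_rule_batch(graph, "20-abstractions.yaml")
  proteins <- unique(kb_find(graph, p = "rdfs:subClassOf",
                             o = "obo:PR_000000001")$s)
  proteins <- proteins[startsWith(proteins, paste0(kb_namespaces()[["kbio"]], "BIO_"))]
  coded <- unique(kb_find(graph, p = "kro:has_indirect_template")$s)
  for (orphan in setdiff(proteins, coded)) {
    kb_log(graph, "WARN OrphanProtein: ", orphan, " has no known coding gene")
  }
  res
}

#' Apply the GO-annotation rules
#'
#' Process (aspect P) annotations yield the 5-triple all-some template -- a
#' new process class subClassOf the annotated GO process and subClassOf a
#' has-participant restriction on the protein; component (aspect C)
#' annotations yield a localization subclass with participant and location
#' restrictions. Restriction nodes are reused, so a binding whose restriction
#' already exists adds 3 fresh triples instead of 5.
#'
#' @param graph A [kb_graph()].
#' @return Emission counts.
#' @export
goa_rule <- function(graph) run_rule_batch(graph, "30-goa.yaml")

#' Apply the drug-gene interaction rule (9-triple pattern)
#'
#' Unresolved participants (a drug or target identifier with no BIO entity)
#' simply do not match; they are counted and logged as UnresolvedParticipant
#' warnings.
#'
#' @param graph A [kb_graph()].
#' @return Emission counts.
#' @export
interaction_rule <- function(graph) {
  res <- run_rule_batch(graph, "40-interactions.yaml")
  # diagnose identifiers in drug_targets records that resolved to no concept
  sc <- kb_schemas()[["drug_targets"]]
  for (fld in c("drug_id", "target_id")) {
    fv <- match_body(list(
      c("?fv", "kiao:has_template", schema_field_uri(sc, fld)),
      c("?fv", "kiao:has_field_value", "?id")), graph)
    if (nrow(fv) == 0L) next
    denoted <- kb_find(graph, p = "iao:denotes")
    bio <- denoted[startsWith(denoted$o, paste0(kb_namespaces()[["kbio"]], "BIO_"))]
    missing <- setdiff(unique(fv$id), unique(bio$s))
    for (m in missing) {
      kb_log(graph, "WARN UnresolvedParticipant: ", m, " has no BIO entity")
    }
  }
  res
}

#' Apply the coarse-grained pathway-participation rule
#'
#' @param graph A [kb_graph()].
#' @return Emission counts.
#' @export
multi_granularity_rules <- function(graph) run_rule_batch(graph, "50-pathways.yaml")

#' Link BIO entities to taxa from source-record taxon fields
#'
#' @param graph A [kb_graph()].
#' @return Emission counts.
#' @export
taxon_links <- function(graph) run_rule_batch(graph, "25-taxon.yaml")

#' Create ICE identifiers for ontology concepts
#'
#' The first rule stage of a build: every ontology class in a registered
#' identifier space (GO terms, taxa) gets a canonical identifier ICE that
#' iao:denotes it, so records can refer to ontology concepts without ever
#' holding a BIO URI -- keeping the ICE-BIO demarcation unambiguous.
#'
#' @param graph A [kb_graph()] with the ontology loaded.
#' @param dialects A [kb_dialects()] table.
#' @param spaces Character vector of spaces whose OBO classes get ICE
#'   identifiers.
#' @return Number of new triples.
#' @export
generate_ontology_ice <- function(graph, dialects = kb_dialects(),
                                  spaces = c("GO", "NCBITaxon")) {
  obo <- kb_namespaces()[["obo"]]
  nodes <- unique(c(graph$dt$s, graph$dt$o[!kb_is_literal(graph$dt$o)]))
  n_add <- 0L
  for (space in spaces) {
    pat <- paste0("^", obo, space, "_([0-9]+)$")
    hits <- nodes[grepl(pat, nodes)]
    if (length(hits) == 0L) next
    local <- sub(pat, "\\1", hits)
    ice <- vapply(local, function(l) canonical_id_uri(space, l, dialects),
                  character(1), USE.NAMES = FALSE)
    trip <- kb_triples(ice, "iao:denotes", hits)
    n_add <- n_add + kb_add(graph, trip)
    kb_record_derivations(graph, data.table::data.table(
      s = trip$s, p = trip$p, o = trip$o, rule = "owl-to-ice",
      binding = sprintf('{"class":"%s"}', hits), records = ""))
  }
  kb_log(graph, "owl-to-ice: ", n_add, " identifier ICE triples")
  n_add
}
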